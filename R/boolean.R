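#' Signed Boolean module networks
#'
#' A `boolean_module_network` is a module-level transcriptional network:
#' ordered module labels, signed inter-module edges with integer
#' multiplicities (parallel interactions between a module pair), optional
#' step-function external input schedules per module, and a set of clamped
#' modules held at a forced value (modelling enforced expression).
#'
#' @param modules character vector of module labels, e.g.
#'   `c("A1","B1","C1","D1","A2","B2","C2","D2")`.
#' @param edges data.frame with columns `source`, `target`, `sign` (+1
#'   promoting / -1 inhibitory) and `multiplicity` (integer >= 1).
#' @param inputs named list (by module) of [input_schedule()] objects.
#' @param clamps named integer/logical vector (by module) of forced values.
#' @param reference_state optional named 0/1 vector over all modules: the
#'   nominal unperturbed initial state used as the robustness reference.
#' @return object of class `boolean_module_network`.
#' @export
boolean_module_network <- function(modules, edges = NULL, inputs = list(),
                                   clamps = NULL, reference_state = NULL) {
  modules <- as.character(modules)
  if (length(modules) < 1) stop("network needs at least one module")
  if (anyDuplicated(modules)) stop("duplicated module label(s)")
  if (is.null(edges) || NROW(edges) == 0)
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), multiplicity = integer())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  bad <- setdiff(unique(c(edges$source, edges$target)), modules)
  if (length(bad) > 0)
    stop("edge endpoint(s) not declared as modules: ", paste(bad, collapse = ", "))
  if (NROW(edges) > 0) {
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1")
    if (any(edges$multiplicity < 1))
      stop("edge multiplicity must be >= 1")
  }
  if (length(inputs) > 0) {
    bad <- setdiff(names(inputs), modules)
    if (length(bad) > 0)
      stop("input schedule(s) on unknown module(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(clamps) && length(clamps) > 0) {
    bad <- setdiff(names(clamps), modules)
    if (length(bad) > 0)
      stop("clamp(s) on unknown module(s): ", paste(bad, collapse = ", "))
    clamps <- stats::setNames(as.integer(clamps), names(clamps))
    if (!all(clamps %in% c(0L, 1L))) stop("clamp values must be 0/1")
  } else clamps <- stats::setNames(integer(0), character(0))
  if (!is.null(reference_state)) {
    if (length(reference_state) != length(modules))
      stop("reference_state length must equal number of modules")
    reference_state <- stats::setNames(as.integer(reference_state), modules)
  }
  # a clamped module that also has an input schedule is legal only when the
  # clamp wins by construction; flag disagreement between a constant
  # schedule and the clamp value to catch inconsistent files early
  for (m in intersect(names(clamps), names(inputs))) {
    sch <- inputs[[m]]
    if (sch$before_value == sch$after_value && sch$before_value != clamps[[m]])
      stop("module ", m, " is clamped to ", clamps[[m]],
           " but carries a constant input of ", sch$before_value)
  }
  structure(list(modules = modules, edges = edges, inputs = inputs,
                 clamps = clamps, reference_state = reference_state),
            class = "boolean_module_network")
}

#' Step-function external input
#'
#' The input contributes `before_value` to a module's net activation for
#' step indices `t < onset_time` and `after_value` for `t >= onset_time`.
#' PMA-like stimulation applied from the start of the run is
#' `input_schedule(0, 1, onset_time = 0)` on the driven module.
#'
#' @param before_value,after_value Boolean (0/1) input levels.
#' @param onset_time step index at which the input switches.
#' @return object of class `input_schedule`.
#' @export
input_schedule <- function(before_value, after_value, onset_time = 0) {
  stopifnot(before_value %in% c(0, 1), after_value %in% c(0, 1))
  structure(list(before_value = as.integer(before_value),
                 after_value = as.integer(after_value),
                 onset_time = as.integer(onset_time)),
            class = "input_schedule")
}

input_value <- function(schedule, t) {
  if (t < schedule$onset_time) schedule$before_value else schedule$after_value
}

#' @export
print.boolean_module_network <- function(x, ...) {
  cat("<boolean_module_network> ", length(x$modules), " modules, ",
      sum(x$edges$multiplicity[x$edges$sign > 0]), " promoting / ",
      sum(x$edges$multiplicity[x$edges$sign < 0]), " inhibitory interactions\n",
      sep = "")
  if (length(x$inputs) > 0)
    cat("  inputs on: ", paste(names(x$inputs), collapse = ", "), "\n", sep = "")
  if (length(x$clamps) > 0)
    cat("  clamps: ", paste(names(x$clamps), x$clamps, sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Net signed weight between two modules
#'
#' Sums `sign * multiplicity` over all parallel edges from `source` to
#' `target`.
#'
#' @param network a `boolean_module_network`.
#' @param source,target module labels.
#' @return signed integer (0 when no edge exists).
#' @export
net_weight <- function(network, source, target) {
  if (!source %in% network$modules || !target %in% network$modules)
    stop("unknown module label")
  e <- network$edges
  sel <- e$source == source & e$target == target
  if (!any(sel)) return(0L)
  as.integer(sum(e$sign[sel] * e$multiplicity[sel]))
}

# modules x modules matrix W with W[j, m] = net weight j -> m
weight_matrix <- function(network) {
  n <- length(network$modules)
  W <- matrix(0, n, n, dimnames = list(network$modules, network$modules))
  e <- network$edges
  for (i in seq_len(NROW(e)))
    W[e$source[i], e$target[i]] <- W[e$source[i], e$target[i]] +
      e$sign[i] * e$multiplicity[i]
  W
}

#' One synchronous update of the network
#'
#' For each non-clamped module `m` the net activation is
#' `s_m = sum_j net_weight(j, m) * state_j + input_m(t)`; the next value is
#' active if `s_m > 0`, inactive if `s_m < 0`, and unchanged if `s_m = 0`
#' (tie-hold).  Clamped modules always take their forced value.  All modules
#' update simultaneously.
#'
#' @param network a `boolean_module_network`.
#' @param state 0/1 vector in module order.
#' @param t step index at which inputs are evaluated.
#' @param rule tie-breaking rule: `"hold"` (keep current value, default) or
#'   `"inactive"` (ties decay to 0).
#' @return next 0/1 state vector (named by module).
#' @export
boolean_step <- function(network, state, t = 0, rule = c("hold", "inactive")) {
  rule <- match.arg(rule)
  state <- as.integer(state)
  n <- length(network$modules)
  if (length(state) != n) stop("state length must equal number of modules")
  W <- attr(network, ".W")
  if (is.null(W)) W <- weight_matrix(network)
  s <- as.numeric(state %*% W)
  if (length(network$inputs) > 0)
    for (m in names(network$inputs))
      s[match(m, network$modules)] <- s[match(m, network$modules)] +
        input_value(network$inputs[[m]], t)
  nxt <- ifelse(s > 0, 1L, ifelse(s < 0, 0L,
                                  if (rule == "hold") state else 0L))
  if (length(network$clamps) > 0)
    nxt[match(names(network$clamps), network$modules)] <- network$clamps
  stats::setNames(as.integer(nxt), network$modules)
}

#' Simulate a Boolean network trajectory
#'
#' Deterministic synchronous iteration of [boolean_step()] for `n_steps`
#' updates.  Clamped modules are forced from `t = 0` on (the supplied
#' initial values of clamped modules are overridden).
#'
#' @inheritParams boolean_step
#' @param initial 0/1 initial state in module order.
#' @param n_steps number of synchronous updates.
#' @return a `state_trajectory` (see [state_trajectory()]) whose `states`
#'   matrix has `n_steps + 1` rows (including `t = 0`).
#' @export
simulate_boolean <- function(network, initial, n_steps = 8,
                             rule = c("hold", "inactive")) {
  rule <- match.arg(rule)
  n <- length(network$modules)
  state <- as.integer(initial)
  if (length(state) != n) stop("initial state length must equal number of modules")
  if (length(network$clamps) > 0)
    state[match(names(network$clamps), network$modules)] <- network$clamps
  attr(network, ".W") <- weight_matrix(network)
  out <- matrix(0L, n_steps + 1, n, dimnames = list(NULL, network$modules))
  out[1, ] <- state
  for (t in seq_len(n_steps)) {
    state <- boolean_step(network, state, t = t - 1L, rule = rule)
    out[t + 1, ] <- state
  }
  state_trajectory(out, run_label = paste(out[1, ], collapse = ""),
                   times = 0:n_steps)
}

#' All 2^n Boolean states of n modules
#'
#' Binary-counting order: the first module toggles fastest, matching
#' [enumerate_perturbations()].
#'
#' @param n_modules number of modules (>= 1).
#' @return matrix with `2^n_modules` rows, one 0/1 state per row.
#' @export
enumerate_states <- function(n_modules) {
  if (n_modules < 1) stop("n_modules must be >= 1")
  if (n_modules > 24) stop("state space too large to enumerate")
  masks <- 0:(2^n_modules - 1)
  vapply(seq_len(n_modules),
         function(b) as.integer(bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0),
         integer(length(masks)))
}

#' Read / write Boolean module-network files
#'
#' YAML or JSON with top-level keys `schema_version`, `modules`, `edges`
#' (`source`/`target`/`sign`/`multiplicity`), optional `inputs` (map module
#' -> `before`/`after`/`onset`), `clamps` (map module -> 0/1) and
#' `reference_state` (map module -> 0/1).
#'
#' @param path file location.
#' @return a validated [boolean_module_network()].
#' @export
read_boolean_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- parse_structured_file(path)
  network_from_list(raw, context = path)
}

#' @rdname read_boolean_network
#' @param network a `boolean_module_network`.
#' @export
write_boolean_network <- function(network, path) {
  obj <- list(
    schema_version = SCHEMA_VERSION,
    modules = as.list(network$modules),
    edges = lapply(seq_len(NROW(network$edges)), function(i)
      list(source = network$edges$source[i], target = network$edges$target[i],
           sign = network$edges$sign[i],
           multiplicity = network$edges$multiplicity[i])),
    inputs = lapply(network$inputs, function(s)
      list(before = s$before_value, after = s$after_value, onset = s$onset_time)),
    clamps = as.list(network$clamps))
  if (!is.null(network$reference_state))
    obj$reference_state <- as.list(network$reference_state)
  write_structured_file(obj, path)
  invisible(path)
}

network_from_list <- function(raw, context = "network") {
  if (is.null(raw$schema_version) || as.integer(raw$schema_version) != SCHEMA_VERSION)
    stop(context, ": missing or unsupported schema_version (this build reads version ",
         SCHEMA_VERSION, ")")
  if (is.null(raw$modules)) stop(context, ": missing modules")
  edges <- if (length(raw$edges) > 0)
    do.call(rbind, lapply(raw$edges, function(e)
      data.frame(source = e$source, target = e$target,
                 sign = as.integer(e$sign),
                 multiplicity = as.integer(e$multiplicity),
                 stringsAsFactors = FALSE)))
  inputs <- lapply(raw$inputs, function(s)
    input_schedule(s$before, s$after, s$onset))
  clamps <- if (length(raw$clamps) > 0) unlist(raw$clamps)
  ref <- if (length(raw$reference_state) > 0)
    unlist(raw$reference_state)[unlist(raw$modules)]
  boolean_module_network(unlist(raw$modules), edges, inputs, clamps, ref)
}

#' Write Boolean trajectories as tidy CSV
#'
#' @param trajectories list of `state_trajectory` objects.
#' @param path output CSV with columns `run_id`, `t`, `module`, `value`.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(run_id = tr$run_label,
               t = rep(tr$times, times = ncol(tr$states)),
               module = rep(colnames(tr$states), each = length(tr$times)),
               value = as.vector(tr$states),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
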