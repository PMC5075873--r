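#' Metabolic perturbation experiment for one single-condition model
#'
#' Runs the exhaustive 2^k doubled-initial perturbation design, discretizes
#' each run into accumulation states, pools the post-initial sample times
#' and returns the variation of state plus the robustness of the final
#' states against the unperturbed run's initial state.
#'
#' @param model single-condition `metabolic_model`.
#' @param duration,sample_interval simulation design (days).
#' @param window entropy pooling window; `NULL` pools
#'   `t in [sample_interval, duration]` (excluding the forced initial
#'   states).
#' @param label condition descriptor carried into the result.
#' @param strict strict (`>`) accumulation threshold, see [discretize()].
#' @param control solver settings.
#' @return a [metrics_result()]; attributes `distribution` (the pooled
#'   [state_distribution()]) and `trajectories` (list of
#'   [state_trajectory()]).
#' @export
metabolic_state_experiment <- function(model, duration = 4, sample_interval = 1,
                                       window = NULL, label = "",
                                       strict = FALSE,
                                       control = solver_control()) {
  perts <- enumerate_perturbations(model)
  runs <- batch_simulate(model, perts, duration, sample_interval, control)
  trajs <- lapply(runs, discretize, model = model, strict = strict)
  if (is.null(window)) window <- c(sample_interval, duration)
  dist <- pool_states(trajs, window)
  rob <- robustness(trajs, trajs[[1]])  # first perturbation is the empty set
  res <- metrics_result(variation_of_state(dist), rob, window,
                        n_runs = length(trajs), label = label)
  attr(res, "distribution") <- dist
  attr(res, "trajectories") <- trajs
  res
}

#' Sweep the interpolation fraction between control and stressed kinetics
#'
#' Evaluates [metabolic_state_experiment()] for every model on the lambda
#' grid `0, 1/32, ..., 1` (33 models): each grid point interpolates all
#' Vmax values linearly between the control (`lambda = 0`) and stressed
#' (`lambda = 1`) sets and reruns the exhaustive perturbation design.
#'
#' @param model two-condition `metabolic_model`.
#' @param duration,sample_interval simulation design (days).
#' @param lambdas grid of blending fractions.
#' @param control solver settings.
#' @return a `lambda_sweep` data.frame with columns `lambda`,
#'   `variation_of_state`, `robustness`, `n_runs`; attribute `window`.
#' @export
lambda_sweep <- function(model, duration = 4, sample_interval = 1,
                         lambdas = seq(0, 32) / 32,
                         control = solver_control()) {
  if (is.unsorted(lambdas, strictly = TRUE))
    stop("lambdas must be strictly increasing")
  rows <- lapply(lambdas, function(lam) {
    res <- metabolic_state_experiment(
      interpolate_vmax(model, lam), duration, sample_interval,
      label = paste0("lambda=", format(lam)), control = control)
    cbind(lambda = lam, as.data.frame(res)[-1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window") <- c(sample_interval, duration)
  class(out) <- c("lambda_sweep", "data.frame")
  out
}

#' Rank-sum comparison of sweep regions
#'
#' Splits the sweep's variation-of-state values at the lambda threshold
#' `cut` and compares the two regions with [wilcoxon_rank_sum()]; on the
#' standard 33-point grid, `cut = 0.375` yields group sizes 12 (below) and
#' 21 (at or above).
#'
#' @param sweep a [lambda_sweep()] result.
#' @param cut lambda threshold.
#' @return list with the group sizes, region medians and the
#'   `rank_sum_report`.
#' @export
region_median_test <- function(sweep, cut = 0.375) {
  lo <- sweep$variation_of_state[sweep$lambda < cut]
  hi <- sweep$variation_of_state[sweep$lambda >= cut]
  if (length(lo) < 1 || length(hi) < 1) stop("cut leaves an empty region")
  list(cut = cut, n_low = length(lo), n_high = length(hi),
       median_low = stats::median(lo), median_high = stats::median(hi),
       test = wilcoxon_rank_sum(lo, hi))
}

#' Enzyme over-expression screen
#'
#' One by one, multiplies each reaction's control Vmax by `factor`
#' (default four-fold), reruns the exhaustive perturbation experiment on the
#' control-condition model and records variation of state and robustness.
#' Two statistics accompany the screen: (a) a one-sided two-sample
#' proportion test comparing the fraction of 'expressed' enzymes between
#' reactions whose variation of state fell below half the (same-run) control
#' value and the rest; (b) a binomial point-probability for the number of
#' expressed-and-changed cases landing in the quadrant where both robustness
#' and variation of state are below control, with quadrant chance 1/4.
#'
#' @param model two-condition `metabolic_model`.
#' @param factor Vmax multiplier.
#' @param annotation data.frame `reaction_id`, `expressed` (0/1) or `NULL`
#'   to skip the two tests.
#' @param duration,sample_interval simulation design (days).
#' @param control solver settings.
#' @return list with `screen` (one row per reaction), `baseline`
#'   (control-model [metrics_result()]), `proportion_test`, `binomial_test`.
#' @export
overexpression_screen <- function(model, factor = 4.0, annotation = NULL,
                                  duration = 4, sample_interval = 1,
                                  control = solver_control()) {
  cond <- model$conditions[1]
  base_model <- select_condition(model, cond)
  baseline <- metabolic_state_experiment(base_model, duration, sample_interval,
                                         label = "control", control = control)
  rids <- names(model$reactions)
  rows <- lapply(rids, function(rid) {
    m <- select_condition(overexpress(model, rid, factor, cond), cond)
    res <- metabolic_state_experiment(m, duration, sample_interval,
                                      label = rid, control = control)
    data.frame(reaction_id = rid,
               variation_of_state = res$variation_of_state,
               robustness = res$robustness, stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, rows)
  screen$below_half_control <-
    screen$variation_of_state < baseline$variation_of_state / 2
  prop_test <- binom_test <- NULL
  if (!is.null(annotation)) {
    screen$expressed <-
      annotation$expressed[match(screen$reaction_id, annotation$reaction_id)] == 1
    if (anyNA(screen$expressed))
      stop("annotation lacks reaction(s): ",
           paste(screen$reaction_id[is.na(screen$expressed)], collapse = ", "))
    lo <- screen[screen$below_half_control, ]
    hi <- screen[!screen$below_half_control, ]
    prop_test <- tryCatch(
      two_sample_proportion(sum(lo$expressed), nrow(lo),
                            sum(hi$expressed), nrow(hi), sided = "one"),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "degenerate_test"))
    changed <- screen$expressed &
      (screen$variation_of_state != baseline$variation_of_state |
         screen$robustness != baseline$robustness)
    both_lower <- changed &
      screen$variation_of_state < baseline$variation_of_state &
      screen$robustness < baseline$robustness
    binom_test <- list(n = sum(changed), k = sum(both_lower), q = 0.25,
                       p = binomial_point(sum(changed), sum(both_lower), 0.25))
  }
  list(screen = screen, baseline = baseline, factor = factor,
       proportion_test = prop_test, binomial_test = binom_test)
}

#' Boolean experiment over all initial conditions
#'
#' Simulates a module network from every one of the 2^n initial states for
#' `n_steps` synchronous updates, pools the states at `t in [1, n_steps]`
#' into the variation of state, and scores robustness of the final states
#' (`t = n_steps`) against the network's `reference_state` (the unperturbed
#' resting pattern at the initial time).
#'
#' @param network a `boolean_module_network` with a `reference_state`.
#' @param n_steps simulation horizon (units of time).
#' @param label condition descriptor.
#' @param rule tie rule passed to [simulate_boolean()].
#' @return a [metrics_result()] with attributes `distribution` and
#'   `trajectories`.
#' @export
boolean_state_experiment <- function(network, n_steps = 8, label = "",
                                     rule = c("hold", "inactive")) {
  rule <- match.arg(rule)
  if (is.null(network$reference_state))
    stop("network has no reference_state for robustness scoring")
  states0 <- enumerate_states(length(network$modules))
  trajs <- lapply(seq_len(nrow(states0)), function(i)
    simulate_boolean(network, states0[i, ], n_steps, rule = rule))
  window <- c(1, n_steps)
  dist <- pool_states(trajs, window)
  ref <- state_trajectory(matrix(network$reference_state, 1,
                                 dimnames = list(NULL, network$modules)),
                          run_label = "reference", times = 0)
  res <- metrics_result(variation_of_state(dist), robustness(trajs, ref),
                        window, n_runs = length(trajs), label = label)
  attr(res, "distribution") <- dist
  attr(res, "trajectories") <- trajs
  res
}

strip_inputs <- function(network) { network$inputs <- list(); network }

#' PMA stimulation experiment
#'
#' Evaluates [boolean_state_experiment()] before (external inputs removed)
#' and after (step inputs active) the stimulus, each over all 2^n initial
#' conditions.
#'
#' @inheritParams boolean_state_experiment
#' @return list with `before` and `after` [metrics_result()]s and the
#'   entropy change as percent of the theoretical maximum
#'   (`percent_of_max`).
#' @export
pma_experiment <- function(network, n_steps = 8, rule = c("hold", "inactive")) {
  rule <- match.arg(rule)
  before <- boolean_state_experiment(strip_inputs(network), n_steps,
                                     label = "inputs off", rule = rule)
  after <- boolean_state_experiment(network, n_steps, label = "inputs on",
                                    rule = rule)
  list(before = before, after = after,
       percent_of_max = percent_of_max(before$variation_of_state,
                                       after$variation_of_state,
                                       2^length(network$modules)))
}

#' Enforced-expression experiments
#'
#' `case1` clamps the differentiation-associated modules (default `A1`,
#' `A2`, `B2`, `C1`) to the active state for the whole run while also
#' applying the step inputs; `case2` clamps the dedifferentiation module
#' (default `B2`) active without supplying the step inputs.  Metrics as in
#' [boolean_state_experiment()].
#'
#' @inheritParams boolean_state_experiment
#' @param case `"case1"` or `"case2"`.
#' @param case1_modules,case2_modules module sets clamped by each case.
#' @return a [metrics_result()].
#' @export
enforced_expression_experiment <- function(network, case = c("case1", "case2"),
                                           n_steps = 8,
                                           case1_modules = c("A1", "A2", "B2", "C1"),
                                           case2_modules = "B2",
                                           rule = c("hold", "inactive")) {
  case <- match.arg(case)
  rule <- match.arg(rule)
  clamp_set <- if (case == "case1") case1_modules else case2_modules
  bad <- setdiff(clamp_set, network$modules)
  if (length(bad) > 0)
    stop("clamped module(s) not in network: ", paste(bad, collapse = ", "))
  net <- network
  if (case == "case2") net <- strip_inputs(net)
  net$clamps <- stats::setNames(rep(1L, length(clamp_set)), clamp_set)
  boolean_state_experiment(net, n_steps, label = case, rule = rule)
}
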