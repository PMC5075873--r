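#' Perturbation of initial metabolite amounts
#'
#' A perturbation doubles the initial amounts of a subset of the model's
#' state metabolites; the empty subset is the unperturbed run.
#'
#' @param doubled_set character vector of state-metabolite ids (may be empty).
#' @return object of class `perturbation`.
#' @export
perturbation <- function(doubled_set = character()) {
  structure(list(doubled_set = as.character(doubled_set)), class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> doubled: ",
      if (length(x$doubled_set) == 0) "(none)" else paste(x$doubled_set, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

perturbation_label <- function(p) {
  if (length(p$doubled_set) == 0) "none" else paste(p$doubled_set, collapse = "+")
}

#' All 2^k perturbations of the declared state metabolites
#'
#' Enumerates every subset of the model's state metabolites (including the
#' empty set) in canonical binary-counting order over the declared
#' metabolite order: the first metabolite toggles fastest.
#'
#' @param model a `metabolic_model` declaring `k >= 1` state metabolites.
#' @return list of `2^k` [perturbation()] objects; the first is the empty
#'   (unperturbed) case.
#' @export
enumerate_perturbations <- function(model) {
  sm <- state_metabolites(model)
  k <- length(sm)
  if (k < 1) stop("model declares no state metabolites")
  lapply(0:(2^k - 1), function(mask) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0
    perturbation(sm[sel])
  })
}

# Flatten a single-condition model into the index vectors consumed by the
# C++ integrator.  Species order follows the metabolite table.
compile_reactions <- function(model, condition = model$conditions[1]) {
  ids <- model$metabolites$id
  idx <- function(m) match(m, ids) - 1L
  sub_off <- integer(0); sub_len <- integer(0)
  sub_idx <- integer(0); sub_coef <- numeric(0); sub_km <- numeric(0)
  prod_off <- integer(0); prod_len <- integer(0)
  prod_idx <- integer(0); prod_coef <- numeric(0)
  vmax <- numeric(0); inh_idx <- integer(0); inh_ki <- numeric(0)
  for (r in model$reactions) {
    sub_off <- c(sub_off, length(sub_idx))
    sub_len <- c(sub_len, NROW(r$substrates))
    if (NROW(r$substrates) > 0) {
      sub_idx <- c(sub_idx, idx(r$substrates$metabolite))
      sub_coef <- c(sub_coef, r$substrates$coef)
      sub_km <- c(sub_km, r$substrates$km)
    }
    prod_off <- c(prod_off, length(prod_idx))
    prod_len <- c(prod_len, NROW(r$products))
    if (NROW(r$products) > 0) {
      prod_idx <- c(prod_idx, idx(r$products$metabolite))
      prod_coef <- c(prod_coef, r$products$coef)
    }
    vmax <- c(vmax, unname(r$vmax[[condition]]))
    if (is.null(r$inhibitor)) {
      inh_idx <- c(inh_idx, -1L); inh_ki <- c(inh_ki, 1)
    } else {
      inh_idx <- c(inh_idx, idx(r$inhibitor$metabolite))
      inh_ki <- c(inh_ki, r$inhibitor$ki)
    }
  }
  list(n_species = length(ids),
       sub_off = as.integer(sub_off), sub_len = as.integer(sub_len),
       sub_idx = as.integer(sub_idx), sub_coef = sub_coef, sub_km = sub_km,
       prod_off = as.integer(prod_off), prod_len = as.integer(prod_len),
       prod_idx = as.integer(prod_idx), prod_coef = prod_coef,
       vmax = vmax, inh_idx = as.integer(inh_idx), inh_ki = inh_ki)
}

#' Solver settings for the kinetic engine
#'
#' @param rtol,atol relative and absolute integration tolerances of the
#'   adaptive Dormand-Prince RK5(4) stepper.
#' @param neg_tol largest tolerated negative excursion: sampled amounts in
#'   `(-neg_tol, 0)` are clipped to 0 (round-off), anything below `-neg_tol`
#'   raises an error (model misspecification).
#' @param max_steps cap on accepted integrator steps per run.
#' @return list of solver settings.
#' @export
solver_control <- function(rtol = 1e-8, atol = 1e-10, neg_tol = 1e-12,
                           max_steps = 1e7) {
  list(rtol = rtol, atol = atol, neg_tol = neg_tol, max_steps = max_steps)
}

#' Simulate a metabolic model
#'
#' Integrates `d[x]/dt = sum(stoichiometry * rate)` for a single-condition
#' model from (optionally perturbed) initial amounts and samples the solution
#' at `t = 0, sample_interval, ..., duration` (days).
#'
#' @param model single-condition `metabolic_model` (see [select_condition()]
#'   or [interpolate_vmax()]).
#' @param perturbation a [perturbation()]; its metabolites start at double
#'   their declared initial amounts.
#' @param duration simulated time span in days.
#' @param sample_interval sampling interval in days; must divide `duration`.
#' @param control solver settings from [solver_control()].
#' @return a `timecourse`: list with `times` (numeric), `amounts` (matrix,
#'   one row per sample time, one column per metabolite) and `run_label`.
#' @export
simulate_timecourse <- function(model, perturbation = statevar::perturbation(),
                                duration = 4, sample_interval = 1,
                                control = solver_control()) {
  if (length(model$conditions) != 1)
    stop("simulate_timecourse needs a single-condition model; use select_condition() or interpolate_vmax()")
  if (duration <= 0) stop("duration must be positive")
  n_int <- duration / sample_interval
  if (abs(n_int - round(n_int)) > 1e-9)
    stop("sample_interval must divide duration")
  bad <- setdiff(perturbation$doubled_set, state_metabolites(model))
  if (length(bad) > 0)
    stop("perturbation names non-state metabolite(s): ", paste(bad, collapse = ", "))
  x0 <- initial_amounts(model)
  x0[perturbation$doubled_set] <- 2 * x0[perturbation$doubled_set]
  times <- seq(0, duration, by = sample_interval)
  sys <- compile_reactions(model)
  amounts <- .ode_solve_cpp(sys, unname(x0), times, control$rtol, control$atol,
                            control$neg_tol, control$max_steps)
  dimnames(amounts) <- list(NULL, model$metabolites$id)
  structure(list(times = times, amounts = amounts,
                 run_label = perturbation_label(perturbation)),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse> run '", x$run_label, "': ", length(x$times),
      " samples x ", ncol(x$amounts), " metabolites over t=[",
      min(x$times), ",", max(x$times), "] days\n", sep = "")
  invisible(x)
}

#' Tidy a timecourse (or write it as CSV)
#'
#' @param x a `timecourse`.
#' @param ... unused.
#' @return data.frame with columns `run_label`, `time_days`, `metabolite_id`,
#'   `amount`.
#' @export
as.data.frame.timecourse <- function(x, ...) {
  data.frame(run_label = x$run_label,
             time_days = rep(x$times, times = ncol(x$amounts)),
             metabolite_id = rep(colnames(x$amounts), each = length(x$times)),
             amount = as.vector(x$amounts),
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.timecourse
#' @param timecourses list of `timecourse` objects.
#' @param path output CSV location.
#' @export
write_timecourses_csv <- function(timecourses, path) {
  df <- do.call(rbind, lapply(timecourses, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Simulate a model under a list of perturbations
#'
#' Deterministically applies [simulate_timecourse()] to each perturbation,
#' preserving order; the first failure is propagated with the perturbation
#' label attached.
#'
#' @inheritParams simulate_timecourse
#' @param perturbations list of [perturbation()] objects, e.g. from
#'   [enumerate_perturbations()].
#' @return list of `timecourse` objects, one per perturbation.
#' @export
batch_simulate <- function(model, perturbations, duration = 4,
                           sample_interval = 1, control = solver_control()) {
  lapply(perturbations, function(p) {
    tryCatch(
      simulate_timecourse(model, p, duration, sample_interval, control),
      error = function(e)
        stop("simulation failed for perturbation '", perturbation_label(p),
             "': ", conditionMessage(e), call. = FALSE))
  })
}
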