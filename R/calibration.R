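#' Observed metabolite time courses
#'
#' Observations are tidy data.frames with columns `condition`,
#' `metabolite_id`, `time_days`, `amount` and `se` (standard error of the
#' replicate mean).  Only fitting-target metabolites are required; all
#' amounts must be positive because the calibration objective is computed
#' on log10 amounts.
#'
#' @param df data.frame in the tidy layout above.
#' @return validated data.frame of class `observed_timecourse`.
#' @export
observed_timecourse <- function(df) {
  need <- c("condition", "metabolite_id", "time_days", "amount", "se")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("observed data lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(df$amount <= 0))
    stop("non-positive observed amount(s) for metabolite(s): ",
         paste(unique(df$metabolite_id[df$amount <= 0]), collapse = ", "),
         " (log10 objective undefined)")
  structure(as.data.frame(df), class = c("observed_timecourse", "data.frame"))
}

#' @rdname observed_timecourse
#' @param path CSV file location.
#' @export
read_observed_csv <- function(path) {
  if (!file.exists(path)) stop("observed-data file not found: ", path)
  observed_timecourse(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname observed_timecourse
#' @param observed an `observed_timecourse`.
#' @export
write_observed_csv <- function(observed, path) {
  utils::write.csv(observed, path, row.names = FALSE)
  invisible(path)
}

# Simulate one condition at arbitrary sample times; returns matrix times x
# metabolites.  Used by calibration where observed times need not be an
# equispaced grid.
ode_sample <- function(model, condition, times, control = solver_control()) {
  single <- select_condition(model, condition)
  sys <- compile_reactions(single)
  times <- sort(unique(c(0, times)))
  amounts <- .ode_solve_cpp(sys, unname(initial_amounts(single)), times,
                            control$rtol, control$atol, control$neg_tol,
                            control$max_steps)
  dimnames(amounts) <- list(NULL, single$metabolites$id)
  list(times = times, amounts = amounts)
}

calibration_objective <- function(model, condition, obs_sub, control) {
  times <- sort(unique(obs_sub$time_days))
  sim <- ode_sample(model, condition, times, control)
  sim_amt <- sim$amounts[match(obs_sub$time_days, sim$times),
                         , drop = FALSE]
  s <- sim_amt[cbind(seq_len(nrow(obs_sub)),
                     match(obs_sub$metabolite_id, colnames(sim_amt)))]
  sum((log10(pmax(s, 1e-12)) - log10(obs_sub$amount))^2)
}

# residuals (log10 sim - log10 obs) and their exact Jacobian w.r.t.
# log10 Vmax, via forward sensitivity integration
calibration_resid_jac <- function(model, condition, obs_sub, control) {
  single <- select_condition(model, condition)
  sys <- compile_reactions(single)
  times <- sort(unique(c(0, obs_sub$time_days)))
  out <- .ode_solve_sens_cpp(sys, unname(initial_amounts(single)), times,
                             control$rtol, control$atol, 1e-8,
                             control$max_steps)
  amounts <- out$amounts
  dimnames(amounts) <- list(NULL, single$metabolites$id)
  ti <- match(obs_sub$time_days, times)
  mi <- match(obs_sub$metabolite_id, colnames(amounts))
  s <- pmax(amounts[cbind(ti, mi)], 1e-12)
  r <- log10(s) - log10(obs_sub$amount)
  vmax <- vapply(single$reactions, function(x) unname(x$vmax[[1]]), numeric(1))
  p <- length(vmax)
  J <- matrix(0, nrow(obs_sub), p)
  for (q in seq_len(p)) {
    dsdv <- out$sens[cbind(ti, mi, q)]
    # d log10(s) / d log10(Vq) = (Vq / s) * ds/dVq
    J[, q] <- vmax[q] * dsdv / s
  }
  list(r = r, J = J)
}

# bounded Levenberg-Marquardt on log10 Vmax with the analytic Jacobian;
# zero-residual problems (noiseless self-consistent data) converge to the
# numerical floor, which plain quasi-Newton descent does not reach along
# the weakly constrained directions
lm_polish <- function(model, condition, obs_sub, start_logv, lb, ub,
                      control, maxit = 80, ftol = 1e-18) {
  rids <- names(model$reactions)
  set_logv <- function(m, logv) {
    for (i in seq_along(rids)) m$reactions[[i]]$vmax[[condition]] <- 10^logv[i]
    m
  }
  p <- pmin(pmax(start_logv, lb), ub)
  rj <- calibration_resid_jac(set_logv(model, p), condition, obs_sub, control)
  f <- sum(rj$r^2)
  lam <- 1e-4
  for (it in seq_len(maxit)) {
    cs <- pmax(sqrt(colSums(rj$J^2)), 1e-12)
    Js <- sweep(rj$J, 2, cs, "/")
    g <- crossprod(Js, rj$r)
    A <- crossprod(Js)
    improved <- FALSE
    repeat {
      step <- tryCatch(solve(A + lam * diag(ncol(A)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        pn <- pmin(pmax(p + as.numeric(step) / cs, lb), ub)
        rjn <- tryCatch(
          calibration_resid_jac(set_logv(model, pn), condition, obs_sub, control),
          error = function(e) NULL)
        if (!is.null(rjn)) {
          fn <- sum(rjn$r^2)
          if (fn < f) {
            p <- pn; rj <- rjn; f <- fn
            lam <- max(lam / 5, 1e-14)
            improved <- TRUE
            break
          }
        }
      }
      lam <- lam * 7
      if (lam > 1e13) break
    }
    if (!improved || f < ftol) break
  }
  list(par = p, value = f, iterations = it)
}

#' Calibrate condition-specific maximum velocities
#'
#' Adjusts every reaction's Vmax in the named condition to minimize the sum
#' of squared differences between log10 simulated and log10 observed amounts
#' over the fitting-target metabolites and their sample times.  The search
#' is bounded local least squares on log10 Vmax from `n_starts` starts
#' (the model's current Vmax values first, then seeded random perturbations
#' of them): a quasi-Newton descent per start, after which the best start is
#' refined by a bounded Levenberg-Marquardt pass using exact
#' forward-sensitivity Jacobians.  The refinement matters on noiseless
#' self-consistent data, where the optimum is a zero-residual point at the
#' bottom of a very ill-conditioned valley that plain descent does not
#' reach.  Ties between starts are broken by the lowest start index.
#'
#' @param model a `metabolic_model`; its current Vmax values for `condition`
#'   are the initial guesses (must be positive).
#' @param observed an [observed_timecourse()] covering at least one fitting
#'   target under `condition`.
#' @param condition condition label to fit.
#' @param n_starts number of optimization starts.
#' @param seed integer seed for the random starts.
#' @param vmax_upper upper bound on every fitted Vmax.
#' @param vmax_lower lower bound (must be > 0 on the log scale).
#' @param maxit L-BFGS-B iteration cap per start.
#' @param polish_maxit Levenberg-Marquardt iteration cap for the final
#'   refinement of the best start (0 disables polishing).
#' @param control solver settings, see [solver_control()].
#' @return the model with the fitted Vmax set for `condition`; attributes
#'   `objective` (best value) and `trace` (one row per start with its final
#'   objective and convergence code).
#' @export
fit_vmax <- function(model, observed, condition, n_starts = 5, seed = 1,
                     vmax_upper = 100, vmax_lower = 1e-4, maxit = 400,
                     polish_maxit = 2000, control = solver_control()) {
  if (!condition %in% model$conditions)
    stop("unknown condition '", condition, "'")
  obs_sub <- observed[observed$condition == condition &
                        observed$metabolite_id %in% fitting_targets(model), ,
                      drop = FALSE]
  if (nrow(obs_sub) == 0)
    stop("observed data covers no fitting-target metabolite under condition '",
         condition, "'")
  if (any(obs_sub$amount <= 0))
    stop("non-positive observed amount(s); log10 objective undefined")
  rids <- names(model$reactions)
  v0 <- vapply(model$reactions, function(r) unname(r$vmax[[condition]]), numeric(1))
  if (any(v0 <= 0)) stop("initial Vmax guesses must be positive")
  set_vmax <- function(m, v) {
    for (i in seq_along(rids)) m$reactions[[i]]$vmax[[condition]] <- v[i]
    m
  }
  obj <- function(logv) {
    calibration_objective(set_vmax(model, 10^logv), condition, obs_sub, control)
  }
  lb <- rep(log10(vmax_lower), length(v0))
  ub <- rep(log10(vmax_upper), length(v0))
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- pmin(pmax(log10(v0), lb), ub)
  for (i in seq_len(n_starts - 1))
    starts[[i + 1]] <- pmin(pmax(log10(v0) + stats::rnorm(length(v0), 0, 0.5),
                                 lb), ub)
  fits <- vector("list", n_starts)
  trace <- data.frame(start = seq_len(n_starts), objective = NA_real_,
                      convergence = NA_integer_)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[[i]], obj, method = "L-BFGS-B", lower = lb,
                   upper = ub,
                   control = list(maxit = maxit, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[i]] <- fit
      trace$objective[i] <- fit$value
      trace$convergence[i] <- fit$convergence
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all optimization starts failed; objective at initial guess = ",
         format(obj(starts[[1]]), digits = 6))
  best <- which(ok)[which.min(trace$objective[ok])]
  par <- fits[[best]]$par
  value <- fits[[best]]$value
  if (polish_maxit > 0) {
    pol <- tryCatch(
      lm_polish(model, condition, obs_sub, par, lb, ub, control,
                maxit = polish_maxit),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < value) {
      par <- pol$par
      value <- pol$value
    }
  }
  fitted <- set_vmax(model, 10^par)
  attr(fitted, "objective") <- value
  attr(fitted, "trace") <- trace
  fitted
}

#' Goodness of fit on the log-log scale
#'
#' Coefficient of determination of log10 simulated against log10 observed
#' amounts, pooled over all fitting targets and their sample times:
#' `r2 = 1 - SS_res / SS_tot` about the mean of the observed logs.  Perfect
#' agreement gives 1; a constant prediction against varying observations
#' gives a value at or below 0.
#'
#' @inheritParams fit_vmax
#' @return `r2` as a single number.
#' @export
goodness_of_fit <- function(model, observed, condition,
                            control = solver_control()) {
  obs_sub <- observed[observed$condition == condition &
                        observed$metabolite_id %in% fitting_targets(model), ,
                      drop = FALSE]
  if (nrow(obs_sub) < 2) stop("need at least 2 matched observations")
  times <- sort(unique(obs_sub$time_days))
  sim <- ode_sample(model, condition, times, control)
  s <- sim$amounts[cbind(match(obs_sub$time_days, sim$times),
                         match(obs_sub$metabolite_id, colnames(sim$amounts)))]
  lo <- log10(obs_sub$amount)
  ls <- log10(pmax(s, 1e-12))
  1 - sum((lo - ls)^2) / sum((lo - mean(lo))^2)
}
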