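#' Discrete state trajectories
#'
#' A `state_trajectory` is the time-indexed sequence of discrete system
#' states of one run: a 0/1 matrix with one row per sample time and one
#' column per state component (state metabolite or network module).
#'
#' @param states 0/1 matrix (rows = times, columns = components).
#' @param run_label perturbation descriptor.
#' @param times sample-time index vector (defaults to `0, 1, ...`).
#' @return object of class `state_trajectory`.
#' @export
state_trajectory <- function(states, run_label = "run", times = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) stop("states must be 0/1")
  if (is.null(times)) times <- seq_len(nrow(states)) - 1
  if (length(times) != nrow(states)) stop("times length must match state rows")
  structure(list(times = times, states = states, run_label = run_label),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory> run '", x$run_label, "': ", nrow(x$states),
      " times x ", ncol(x$states), " components\n", sep = "")
  invisible(x)
}

#' Discretize a metabolic timecourse into accumulation states
#'
#' A state metabolite is *accumulated* at a sample time when its amount
#' reaches at least double its unperturbed declared initial amount (the
#' baseline comes from the model, not from the possibly perturbed run), so a
#' doubled-initial perturbation registers as accumulated at `t = 0`.  With
#' `strict = TRUE` the comparison is strictly greater than double, the
#' literal reading of "more than double".
#'
#' @param timecourse a `timecourse` from [simulate_timecourse()].
#' @param model the `metabolic_model` declaring baselines and state
#'   metabolites.
#' @param strict use `>` instead of the default `>=` at exactly 2x.
#' @return a [state_trajectory()] over the state metabolites.
#' @export
discretize <- function(timecourse, model, strict = FALSE) {
  sm <- state_metabolites(model)
  missing_m <- setdiff(sm, colnames(timecourse$amounts))
  if (length(missing_m) > 0)
    stop("timecourse lacks state metabolite(s): ", paste(missing_m, collapse = ", "))
  baseline <- initial_amounts(model)[sm]
  amt <- timecourse$amounts[, sm, drop = FALSE]
  thresh <- matrix(2 * baseline, nrow(amt), length(sm), byrow = TRUE)
  states <- if (strict) amt > thresh else amt >= thresh
  state_trajectory(states * 1L, run_label = timecourse$run_label,
                   times = timecourse$times)
}

state_keys <- function(states) apply(states, 1, paste, collapse = "")

#' Empirical distribution over discrete states
#'
#' @param counts named non-negative integer vector; names are state
#'   bit-pattern strings (component order preserved).
#' @param n_components tuple length.
#' @return object of class `state_distribution` with fields `counts`,
#'   `total` and `n_components`.
#' @export
state_distribution <- function(counts, n_components) {
  counts <- counts[counts > 0]
  structure(list(counts = counts, total = sum(counts),
                 n_components = as.integer(n_components)),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("<state_distribution> ", length(x$counts), " distinct states, total ",
      x$total, " observations (", x$n_components, "-tuples)\n", sep = "")
  invisible(x)
}

#' Pool state occurrences from trajectories
#'
#' Counts every state occurrence across all runs and all sample times within
#' the inclusive window `[window[1], window[2]]`.  The default window for
#' entropy excludes `t = 0` (the forced initial conditions) and runs to the
#' final time.
#'
#' @param trajectories list of [state_trajectory()] objects with identical
#'   tuple length.
#' @param window inclusive `(t_start, t_end)`; `NULL` uses
#'   `(first time after 0, final time)` and falls back to the full range for
#'   single-time trajectories.
#' @return a [state_distribution()].
#' @export
pool_states <- function(trajectories, window = NULL) {
  if (length(trajectories) == 0) stop("no trajectories to pool")
  nc <- unique(vapply(trajectories, function(tr) ncol(tr$states), integer(1)))
  if (length(nc) != 1) stop("trajectories have differing tuple lengths")
  if (is.null(window)) {
    tmax <- max(trajectories[[1]]$times)
    after0 <- trajectories[[1]]$times[trajectories[[1]]$times > 0]
    window <- if (length(after0) > 0) c(min(after0), tmax) else c(0, tmax)
  }
  acc <- empty_state_counter(nc)
  for (tr in trajectories) acc <- add_states(acc, tr, window)
  dist <- state_distribution(acc$counts, nc)
  attr(dist, "window") <- window
  dist
}

#' Streaming state counting
#'
#' `empty_state_counter()` starts an accumulator and `add_states()` folds one
#' trajectory into it; [pool_states()] is the batch equivalent (and is itself
#' implemented as this fold).  Useful when trajectories are produced one at a
#' time and should not all be held in memory.
#'
#' @param n_components tuple length.
#' @return an accumulator list with fields `counts` and `n_components`.
#' @export
empty_state_counter <- function(n_components) {
  list(counts = stats::setNames(integer(0), character(0)),
       n_components = as.integer(n_components))
}

#' @rdname empty_state_counter
#' @param counter accumulator from `empty_state_counter()`.
#' @param trajectory a [state_trajectory()].
#' @param window inclusive `(t_start, t_end)` time window.
#' @export
add_states <- function(counter, trajectory, window) {
  if (ncol(trajectory$states) != counter$n_components)
    stop("tuple length mismatch")
  sel <- trajectory$times >= window[1] & trajectory$times <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] selects no samples in run '", trajectory$run_label, "'")
  keys <- state_keys(trajectory$states[sel, , drop = FALSE])
  tab <- table(keys)
  for (k in names(tab)) {
    counter$counts[k] <- (if (k %in% names(counter$counts)) counter$counts[[k]] else 0L) +
      as.integer(tab[[k]])
  }
  counter
}

#' Variation of state (Shannon entropy, bits)
#'
#' `H = -sum_x P(x) log2 P(x)` with `P(x) = counts(x)/total` and
#' `0 log 0 := 0`.  `H` is 0 when a single state carries all mass and
#' reaches its maximum `log2(n)` on the uniform distribution over `n`
#' states.
#'
#' @param dist a [state_distribution()].
#' @return entropy in bits.
#' @export
variation_of_state <- function(dist) {
  if (dist$total <= 0) stop("empty state distribution")
  p <- dist$counts / dist$total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Robustness against perturbation
#'
#' For each perturbed run, each module (state component) scores 1 when its
#' state at the final observation time equals the unperturbed reference
#' run's state at the initial observation time; robustness `R` is the mean
#' of these indicators over all modules and all runs, so `R` is 1 for a
#' system whose perturbed runs all return to the unperturbed initial state
#' and 0 when no component ever matches.
#'
#' @param perturbed list of [state_trajectory()] objects.
#' @param reference the unperturbed [state_trajectory()] (its `t = 0` row is
#'   the reference state).
#' @return `R` in `[0, 1]`.
#' @export
robustness <- function(perturbed, reference) {
  if (length(perturbed) == 0) stop("no perturbed trajectories")
  ref0 <- reference$states[1, ]
  matches <- vapply(perturbed, function(tr) {
    if (ncol(tr$states) != length(ref0)) stop("tuple length mismatch")
    mean(tr$states[nrow(tr$states), ] == ref0)
  }, numeric(1))
  mean(matches)
}

#' Entropy change as a percentage of the theoretical maximum
#'
#' `100 * (h_before - h_after) / log2(n_states)`, rounded to the nearest
#' integer percent.  Positive values are losses of variation of state,
#' negative values gains.
#'
#' @param h_before,h_after entropies in bits.
#' @param n_states size of the discrete state space (>= 2); the theoretical
#'   maximum entropy is `log2(n_states)`.
#' @return signed integer percent.
#' @export
percent_of_max <- function(h_before, h_after, n_states) {
  if (n_states < 2) stop("n_states must be >= 2")
  as.integer(round(100 * (h_before - h_after) / log2(n_states)))
}

#' Bundle the two statistics of one experimental condition
#'
#' @param variation_of_state entropy in bits.
#' @param robustness fraction in `[0, 1]`.
#' @param window `(t_start, t_end)` pooling window.
#' @param n_runs number of perturbation runs pooled.
#' @param label condition descriptor.
#' @return object of class `metrics_result`.
#' @export
metrics_result <- function(variation_of_state, robustness, window, n_runs,
                           label = "") {
  structure(list(variation_of_state = variation_of_state,
                 robustness = robustness, window = window, n_runs = n_runs,
                 label = label),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat("<metrics_result", if (nzchar(x$label)) paste0(" '", x$label, "'"), "> ",
      "variation of state = ", format(x$variation_of_state, digits = 4),
      " bit, robustness = ", format(x$robustness, digits = 4),
      " (window [", x$window[1], ", ", x$window[2], "], ", x$n_runs, " runs)\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.metrics_result <- function(x, ...) {
  data.frame(label = x$label, variation_of_state = x$variation_of_state,
             robustness = x$robustness, window_start = x$window[1],
             window_end = x$window[2], n_runs = x$n_runs,
             stringsAsFactors = FALSE)
}

#' Tidy CSV of a state distribution
#'
#' One row per distinct state: bit-pattern string, count and probability.
#'
#' @param dist a [state_distribution()].
#' @param path output CSV location (`NULL` returns the data.frame only).
#' @return the data.frame, invisibly when written.
#' @export
write_state_distribution_csv <- function(dist, path = NULL) {
  ord <- order(names(dist$counts))
  df <- data.frame(state = names(dist$counts)[ord],
                   count = as.integer(dist$counts[ord]),
                   probability = as.numeric(dist$counts[ord] / dist$total),
                   stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
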