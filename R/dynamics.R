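#' Time-resolved two-state trajectory
#'
#' @param states Integer vector of state labels (1 or 2), one per frame.
#' @param dt Frame spacing in ns (> 0).
#' @param boundary Optional assignment threshold in parameter units (for
#'   trajectories produced by [assign_states()]).
#' @return Object of class `state_trajectory`.
#' @export
state_trajectory <- function(states, dt, boundary = NA_real_) {
  states <- as.integer(states)
  stopifnot(length(states) >= 1L, dt > 0, all(states %in% c(1L, 2L)))
  structure(list(states = states, dt = dt, boundary = boundary,
                 n = length(states)),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d frames, dt = %g ns, occupancy(1) = %.3f\n",
              x$n, x$dt, mean(x$states == 1L)))
  invisible(x)
}

#' Assign trajectory frames to conformational substates
#'
#' Hard frame-wise assignment: each frame goes to the mixture component with
#' the larger posterior responsibility under a fitted binormal model (ties to
#' state 1, the lower-mean component). No hidden-Markov smoothing is applied;
#' this mirrors a direct threshold reading of the time series. The recorded
#' `boundary` is the crossing point of the two weighted component densities
#' between the means.
#'
#' @param series A [helical_ensemble()] carrying a `time` vector with a
#'   uniform timestep (relative tolerance 1e-6).
#' @param fit A [binormal_fit()] (must have converged) or [binormal_spec()].
#' @param min_dwell_frames Optional minimum dwell length in frames; shorter
#'   excursions are merged back into the surrounding state (default 0 = no
#'   filtering; fast recrossings then count as transitions).
#' @return A [state_trajectory()].
#' @export
assign_states <- function(series, fit, min_dwell_frames = 0L) {
  stopifnot(inherits(series, "helical_ensemble"))
  if (is.null(series$time) || series$n < 2L)
    stop("series must carry a time vector with at least 2 frames")
  dts <- diff(series$time)
  dt <- dts[1L]
  bad <- which(abs(dts - dt) > 1e-6 * abs(dt))
  if (length(bad) > 0L)
    stop("non-uniform timestep starting at frame index ", bad[1L] + 1L)
  if (inherits(fit, "binormal_fit") && !isTRUE(fit$converged))
    stop("binormal fit did not converge; refusing to assign states")
  m <- if (inherits(fit, "binormal_fit")) fit$model else fit
  # compare log posterior weights directly so an exact tie goes to state 1
  a <- log(m$p_r) + dnorm(series$values, m$mu1, m$sigma1, log = TRUE)
  b <- log1p(-m$p_r) + dnorm(series$values, m$mu2, m$sigma2, log = TRUE)
  states <- ifelse(a >= b, 1L, 2L)
  if (min_dwell_frames > 0L) states <- filter_min_dwell(states, min_dwell_frames)
  state_trajectory(states, dt, boundary = density_crossing(m))
}

# crossing of the weighted component densities between the means
density_crossing <- function(m) {
  lo <- min(m$mu1, m$mu2); hi <- max(m$mu1, m$mu2)
  if (hi - lo < .Machine$double.eps^0.5) return((lo + hi) / 2)
  f <- function(x)
    (log(m$p_r) + dnorm(x, m$mu1, m$sigma1, log = TRUE)) -
    (log1p(-m$p_r) + dnorm(x, m$mu2, m$sigma2, log = TRUE))
  if (f(lo) * f(hi) > 0) return((lo + hi) / 2)   # no crossing between means
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# merge dwells shorter than k frames into the preceding state
filter_min_dwell <- function(states, k) {
  r <- rle(states)
  short <- which(r$lengths < k)
  short <- short[short > 1L]
  for (i in short) r$values[i] <- r$values[i - 1L]
  # re-merge identical neighbours
  out <- inverse.rle(r)
  inverse.rle(rle(out))
}

#' Transition counts, rates, residence times and occupancies
#'
#' `n_transitions` counts every state change (both directions), so the rate
#' is the total two-way transition frequency per ns. Mean residence times use
#' completed dwells only: the first and last dwell of the trajectory are
#' censored (their true length is unknown) and excluded.
#'
#' @param traj A [state_trajectory()] with at least 2 frames.
#' @return List with `n_transitions`, `rate_per_ns`, `mean_residence`
#'   (named per-state vector, ns; `NA` when a state has no completed
#'   dwell) and `occupancy` (named frame fractions).
#' @export
transition_stats <- function(traj) {
  stopifnot(inherits(traj, "state_trajectory"), traj$n >= 2L)
  s <- traj$states
  n_trans <- sum(diff(s) != 0L)
  duration <- traj$dt * (traj$n - 1L)
  r <- rle(s)
  res <- c(`1` = NA_real_, `2` = NA_real_)
  if (length(r$lengths) > 2L) {
    lens <- r$lengths[-c(1L, length(r$lengths))]
    vals <- r$values[-c(1L, length(r$values))]
    for (st in 1:2)
      if (any(vals == st))
        res[as.character(st)] <- mean(lens[vals == st]) * traj$dt
  }
  list(n_transitions = n_trans,
       rate_per_ns = n_trans / duration,
       mean_residence = res,
       occupancy = c(`1` = mean(s == 1L), `2` = mean(s == 2L)))
}

#' Windowed convergence diagnostics of a two-state series
#'
#' Recomputes the occupancy of the low state and the transition rate on
#' growing prefix windows of the trajectory — the standard check that a short
#' trajectory overestimates the population of its initial substate — and on
#' `n_blocks` consecutive equal blocks, to test whether the transition
#' frequency is constant along the whole trajectory.
#'
#' @param series A [helical_ensemble()] with `time`.
#' @param fit A converged [binormal_fit()] or a [binormal_spec()].
#' @param windows Ascending vector of window durations (ns), each at most
#'   the total duration.
#' @param n_blocks Number of equal consecutive blocks for the block-rate
#'   check (default 10).
#' @return Data frame with one row per window (`window_ns`,
#'   `occupancy_low`, `rate_per_ns`) plus attributes `block_rates` and
#'   `max_block_rel_dev` (largest relative deviation of a block rate from
#'   the mean block rate).
#' @export
convergence_profile <- function(series, fit, windows, n_blocks = 10L) {
  traj <- assign_states(series, fit)
  duration <- traj$dt * (traj$n - 1L)
  stopifnot(length(windows) >= 1L)
  if (is.unsorted(windows)) stop("windows must be ascending")
  if (any(windows > duration + 1e-9))
    stop("window exceeds trajectory duration")
  rows <- lapply(windows, function(w) {
    nw <- max(2L, min(traj$n, floor(w / traj$dt) + 1L))
    st <- transition_stats(state_trajectory(traj$states[seq_len(nw)], traj$dt))
    data.frame(window_ns = w,
               occupancy_low = st$occupancy[["1"]],
               rate_per_ns = st$rate_per_ns)
  })
  out <- do.call(rbind, rows)
  # block analysis on the full series
  nb <- min(n_blocks, traj$n %/% 2L)
  block_id <- cut(seq_len(traj$n), nb, labels = FALSE)
  block_rates <- vapply(seq_len(nb), function(b) {
    s <- traj$states[block_id == b]
    if (length(s) < 2L) return(NA_real_)
    sum(diff(s) != 0L) / (traj$dt * (length(s) - 1L))
  }, numeric(1))
  attr(out, "block_rates") <- block_rates
  mb <- mean(block_rates, na.rm = TRUE)
  attr(out, "max_block_rel_dev") <-
    if (mb > 0) max(abs(block_rates - mb), na.rm = TRUE) / mb else 0
  out
}
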