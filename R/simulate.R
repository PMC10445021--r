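# Stochastic simulation of the alternating-renewal gating process.
#
# RNG policy: each exported simulator takes one root seed; multi-trajectory
# estimators derive an independent child seed per trajectory with
# .child_seed(), so results do not depend on how trajectories are batched.

.child_seed <- function(seed, i) {
  ((as.double(seed) %% 1e5) * 20011 + as.double(i) * 7919) %% 2147483647
}

#' Sample a gating trajectory
#'
#' Simulates the alternating-renewal process: the residence time in each
#' state is drawn from that state's dwell law by inverse-CDF sampling, and
#' the process moves along the scheme's chain (with the competing-risks
#' branch at `C2` for the three-state chain).  The final dwell is capped at
#' the simulation end and flagged `truncated`; truncated dwells are
#' excluded from [dwell_statistics()] to avoid length-biased estimates.
#'
#' @param scheme a [gating_scheme()].
#' @param start_state label of the initial state.
#' @param duration total simulated time (s, > 0).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return An object of class `gating_trajectory`: list with `start_state`,
#'   `dwells` (data frame `state`, `duration_s`, `truncated`) and
#'   `total_duration`.
#' @examples
#' sch <- two_state_scheme(dwell_law("exponential", rate = 2),
#'                         dwell_law("exponential", rate = 1))
#' tr <- sample_trajectory(sch, "C", duration = 10, seed = 1)
#' head(tr$dwells)
#' @export
sample_trajectory <- function(scheme, start_state, duration, seed = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"), duration > 0)
  if (!start_state %in% scheme$states$label)
    stop("unknown start_state '", start_state, "'; states: ",
         paste(scheme$states$label, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (scheme$topology == "two_state") {
    dw <- .sample_two_state_dwells(scheme, start_state, duration)
  } else {
    dw <- .sample_three_state_dwells(scheme, start_state, duration)
  }
  cum <- cumsum(dw$duration_s)
  keep <- which(cum - dw$duration_s < duration)
  dw <- dw[keep, , drop = FALSE]
  cum <- cum[keep]
  n <- nrow(dw)
  dw$truncated <- FALSE
  if (cum[n] > duration) {
    dw$duration_s[n] <- duration - (cum[n] - dw$duration_s[n])
    dw$truncated[n] <- TRUE
  }
  rownames(dw) <- NULL
  structure(list(start_state = start_state, dwells = dw,
                 total_duration = duration),
            class = "gating_trajectory")
}

.sample_two_state_dwells <- function(scheme, start_state, duration) {
  lawA <- scheme$dwell_laws[[start_state]]
  other <- setdiff(c("C", "O"), start_state)
  lawB <- scheme$dwell_laws[[other]]
  mA <- dwell_mean(lawA); mB <- dwell_mean(lawB)
  n_cyc <- if (is.finite(mA + mB))
    ceiling(duration / (mA + mB) * 1.3) + 8 else 16L
  states <- character(0); durs <- numeric(0); total <- 0
  repeat {
    dA <- sample_dwell(lawA, n_cyc)
    dB <- sample_dwell(lawB, n_cyc)
    inter <- as.vector(rbind(dA, dB))
    states <- c(states, rep(c(start_state, other), n_cyc))
    durs <- c(durs, inter)
    total <- total + sum(inter)
    if (total >= duration) break
    n_cyc <- max(n_cyc, 16L)
  }
  data.frame(state = states, duration_s = durs, stringsAsFactors = FALSE)
}

.sample_three_state_dwells <- function(scheme, start_state, duration) {
  states <- character(0); durs <- numeric(0)
  s <- start_state; total <- 0
  repeat {
    d <- sample_dwell(scheme$dwell_laws[[s]], 1L)
    states <- c(states, s); durs <- c(durs, d)
    total <- total + d
    if (total >= duration) break
    u <- if (s == "C2") stats::runif(1) else 0
    s <- .next_state(scheme, s, u)
  }
  data.frame(state = states, duration_s = durs, stringsAsFactors = FALSE)
}

#' @export
print.gating_trajectory <- function(x, ...) {
  cat("<gating_trajectory> start", x$start_state, "-", nrow(x$dwells),
      "dwells over", x$total_duration, "s\n")
  invisible(x)
}

#' State occupancy by Monte Carlo
#'
#' Estimates state probabilities on a time grid as the fraction of
#' independent trajectories occupying each state, with per-point binomial
#' standard errors for the open state.  Each trajectory runs on its own
#' deterministically derived child seed, so the estimate does not depend on
#' batching order.
#'
#' @param scheme a [gating_scheme()].
#' @param start_state label of the initial state.
#' @param grid ascending time grid starting at 0 (s).
#' @param n_traj number of trajectories (>= 1).
#' @param seed root integer seed.
#' @return An `occupancy_curve` data frame: `time`, `p_open`, `p_closed`
#'   (plus `p_c1`, `p_c2` for the three-state chain) and `stderr`; the
#'   attribute `n_trajectories` records the sample size.
#' @export
mc_occupancy <- function(scheme, start_state, grid, n_traj, seed = 1) {
  stopifnot(inherits(scheme, "gating_scheme"), n_traj >= 1)
  if (length(grid) == 0) stop("empty time grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE) || grid[1] != 0)
    stop("grid must be strictly ascending and start at 0", call. = FALSE)
  labs <- scheme$states$label
  G <- length(grid)
  counts <- matrix(0L, nrow = length(labs), ncol = G,
                   dimnames = list(labs, NULL))
  horizon <- max(grid) * (1 + 1e-12) + .Machine$double.eps
  cols <- seq_len(G)
  for (i in seq_len(n_traj)) {
    tr <- sample_trajectory(scheme, start_state, duration = horizon,
                            seed = .child_seed(seed, i))
    cum <- cumsum(tr$dwells$duration_s)
    idx <- findInterval(grid, cum, left.open = FALSE) + 1L
    idx[idx > nrow(tr$dwells)] <- nrow(tr$dwells)
    s_idx <- match(tr$dwells$state[idx], labs)
    counts[cbind(s_idx, cols)] <- counts[cbind(s_idx, cols)] + 1L
  }
  p <- counts / n_traj
  out <- data.frame(time = grid, p_open = p["O", ])
  if (scheme$topology == "two_state") {
    out$p_closed <- p["C", ]
  } else {
    out$p_closed <- p["C1", ] + p["C2", ]
    out$p_c1 <- p["C1", ]
    out$p_c2 <- p["C2", ]
  }
  out$stderr <- sqrt(out$p_open * (1 - out$p_open) / n_traj)
  attr(out, "n_trajectories") <- n_traj
  class(out) <- c("occupancy_curve", "data.frame")
  out
}

#' Closed-form two-state master-equation occupancy
#'
#' Markov special case with constant rates:
#' \eqn{p_O(t) = p_\infty + (p_O(0) - p_\infty) e^{-(k_o + k_c)t}} with
#' \eqn{p_\infty = k_o/(k_o + k_c)}.
#'
#' @param k_open,k_close opening and closing rates (1/s, > 0).
#' @param p_open0 open probability at `t = 0`.
#' @param grid time grid (s).
#' @return An `occupancy_curve` data frame (analytic: `stderr` 0,
#'   `n_trajectories` attribute 0).
#' @export
master_equation_occupancy <- function(k_open, k_close, p_open0, grid) {
  stopifnot(k_open > 0, k_close > 0, p_open0 >= 0, p_open0 <= 1)
  p_inf <- k_open / (k_open + k_close)
  p <- p_inf + (p_open0 - p_inf) * exp(-(k_open + k_close) * grid)
  out <- data.frame(time = grid, p_open = p, p_closed = 1 - p, stderr = 0)
  attr(out, "n_trajectories") <- 0L
  class(out) <- c("occupancy_curve", "data.frame")
  out
}

#' Per-state residence statistics of simulated trajectories
#'
#' Arithmetic mean residence time of completed dwells per state (truncated
#' final dwells are excluded), event counts, and the effective rate
#' reported as the reciprocal mean \eqn{1/\langle\tau\rangle}.  A state
#' with no completed dwell is flagged missing (`NA` statistics), never
#' reported as zero.
#'
#' @param trajs a `gating_trajectory`, a list of them, or a dwell event
#'   data frame with columns `state` and `duration_s` (and optionally
#'   `truncated`).
#' @return Data frame with one row per state: `state`, `n_events`,
#'   `mean_residence_s`, `effective_rate_per_s`.
#' @examples
#' ev <- data.frame(state = c("C", "O", "C"), duration_s = c(2, 1, 4))
#' dwell_statistics(ev)  # <tau_C> = 3 s, <tau_O> = 1 s
#' @export
dwell_statistics <- function(trajs) {
  ev <- .as_event_frame(trajs)
  if (!is.null(ev$truncated)) ev <- ev[!ev$truncated, , drop = FALSE]
  states <- unique(ev$state)
  if (nrow(ev) == 0)
    stop("no completed dwells to summarise", call. = FALSE)
  res <- do.call(rbind, lapply(states, function(s) {
    d <- ev$duration_s[ev$state == s]
    data.frame(state = s, n_events = length(d),
               mean_residence_s = if (length(d)) mean(d) else NA_real_,
               effective_rate_per_s = if (length(d)) 1 / mean(d)
                                      else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

.as_event_frame <- function(trajs) {
  if (inherits(trajs, "gating_trajectory")) return(trajs$dwells)
  if (is.data.frame(trajs)) {
    stopifnot(all(c("state", "duration_s") %in% names(trajs)))
    return(trajs)
  }
  if (is.list(trajs)) {
    return(do.call(rbind, lapply(trajs, .as_event_frame)))
  }
  stop("expected a gating_trajectory, a list of them, or an event ",
       "data frame", call. = FALSE)
}

#' Write / read dwell event lists as delimited text
#'
#' Event lists use a two-column CSV with header `state,duration_s`.
#'
#' @param events event data frame (`state`, `duration_s`).
#' @param path file path.
#' @return `write_dwell_events` returns `path` invisibly;
#'   `read_dwell_events` returns the event data frame.
#' @export
write_dwell_events <- function(events, path) {
  ev <- .as_event_frame(events)
  utils::write.csv(ev[c("state", "duration_s")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dwell_events
#' @export
read_dwell_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("state", "duration_s") %in% names(ev)))
  ev
}
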