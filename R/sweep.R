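#' Effective opening/closing rates across a temperature grid
#'
#' Couples temperature to the gating scheme through the Eyring rates: at
#' each temperature the dwell law of every closed state is rescaled so its
#' mean residence time equals `1/rate_constant(thermo, "open_transition", T)`
#' and the open-state law to the reciprocal closing rate, leaving shape
#' parameters fixed (the minimal temperature coupling for non-exponential
#' laws).  Effective rates are the reciprocal mean residence times, either
#' exactly (`method = "analytic"`, where the mean is matched by
#' construction) or estimated from simulated trajectories via
#' [dwell_statistics()] (`method = "mc"`).  Opening and closing curves are
#' permitted to be -- and with unequal barriers are -- asymmetric.
#'
#' @param thermo a [thermo_params()].
#' @param scheme a [gating_scheme()].
#' @param T_grid temperatures in kelvin, all within (250, 400).
#' @param method `"analytic"` or `"mc"`.
#' @param n_traj,duration,seed Monte-Carlo controls (ignored for
#'   `"analytic"`); `duration` defaults to 200 mean gating cycles.
#' @return Data frame with columns `temperature_K`, `k_open_eff`,
#'   `k_close_eff` (1/s).
#' @export
temperature_rate_sweep <- function(thermo, scheme, T_grid,
                                   method = c("analytic", "mc"),
                                   n_traj = 20L, duration = NULL,
                                   seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(thermo, "thermo_params"),
            inherits(scheme, "gating_scheme"))
  if (any(T_grid <= 250) || any(T_grid >= 400))
    stop("temperatures must lie within (250, 400) K", call. = FALSE)
  closed_labels <- scheme$states$label[scheme$states$conductance_weight == 0]
  out <- lapply(T_grid, function(Tk) {
    k_o <- rate_constant(thermo, "open_transition", Tk)
    k_c <- rate_constant(thermo, "close_transition", Tk)
    if (method == "analytic")
      return(data.frame(temperature_K = Tk, k_open_eff = k_o,
                        k_close_eff = k_c))
    laws <- scheme$dwell_laws
    for (lab in closed_labels)
      laws[[lab]] <- dwell_rescale_mean(laws[[lab]], 1 / k_o)
    laws$O <- dwell_rescale_mean(laws$O, 1 / k_c)
    sch_T <- gating_scheme(scheme$topology, laws,
                           p_c2_open = if (is.null(scheme$p_c2_open)) 0.5
                                       else scheme$p_c2_open,
                           o_reentry = if (is.null(scheme$o_reentry)) "C2"
                                       else scheme$o_reentry)
    dur <- if (is.null(duration)) 200 * (1 / k_o + 1 / k_c) else duration
    trs <- lapply(seq_len(n_traj), function(i)
      sample_trajectory(sch_T, closed_labels[1], dur,
                        seed = .child_seed(seed + round(Tk * 10), i)))
    st <- dwell_statistics(trs)
    mean_closed <- sum(st$mean_residence_s[st$state %in% closed_labels] *
                         st$n_events[st$state %in% closed_labels]) /
      sum(st$n_events[st$state %in% closed_labels])
    data.frame(temperature_K = Tk,
               k_open_eff = 1 / mean_closed,
               k_close_eff = st$effective_rate_per_s[st$state == "O"])
  })
  do.call(rbind, out)
}
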