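# Synthetic G-T-V datasets and dwell-time event lists emulating the
# structure of TRPV1-like (heat-activated) and TRPM8-like (cold-activated)
# whole-cell recordings: a voltage ladder from -120 to +160 mV in 20 mV
# steps, and conductance-temperature curves spanning the activation
# transition.  Default thermodynamic parameters are synthetic conventions
# chosen for the right activation polarity and steepness (T* near 315 K
# for the heat-activated profile, near 288 K for the cold-activated one);
# they are stand-ins, not fitted experimental values.

#' Generator profile for synthetic conductance datasets
#'
#' Bundles the thermodynamic truth, grids, voltage modulation, noise level
#' and seed from which [generate_gv_dataset()] produces a fully
#' reproducible dataset.
#'
#' Default profiles:
#' \describe{
#'   \item{`trpv1_like`}{heat-activated: `dH = 200` kJ/mol, `dS = 635`
#'     J/(mol K) (`T* ~ 315` K, i.e. activation above ~42 C),
#'     temperatures 296-331 K in 5 K steps.}
#'   \item{`trpm8_like`}{cold-activated: `dH = -150` kJ/mol, `dS = -520`
#'     J/(mol K) (`T* ~ 288` K), temperatures 273-308 K.}
#' }
#' Both use the standard voltage ladder (-120 to +160 mV, 20 mV steps), a
#' multiplicative Boltzmann voltage factor with `v_half_mod = 0` mV and
#' `v_slope_mod = 40` mV, and homoscedastic truncated-Gaussian noise
#' (`noise_sd = 0.02`, clipped to [0, 1]).
#'
#' @param name `"trpv1_like"`, `"trpm8_like"` or `"custom"`.
#' @param thermo a [thermo_params()]; required for `"custom"`, otherwise
#'   overrides the profile default.
#' @param T_grid temperatures (K).
#' @param V_ladder voltages (mV); default -120..+160 step 20.
#' @param noise_sd conductance noise SD (>= 0).
#' @param n_replicates replicate sweeps per (T, V) condition.
#' @param v_half_mod,v_slope_mod voltage-modulation Boltzmann parameters
#'   (mV).
#' @param memory_Ea activation energy (J/mol) of the memory rate `k_c1`
#'   when the profile's `thermo` carries `k_c1 * tau_r > 0`; see
#'   [epsilon_with_memory()].
#' @param memory_T_ref reference temperature (K) at which `k_c1 * tau_r`
#'   equals the value stored in `thermo`.
#' @param heteroscedastic if `TRUE`, noise SD scales as
#'   `noise_sd * 4 * g(1-g)` instead of being constant.
#' @param seed integer seed; the dataset is a pure function of
#'   (profile, seed).
#' @return An object of class `generator_profile`.
#' @export
generator_profile <- function(name = c("trpv1_like", "trpm8_like",
                                       "custom"),
                              thermo = NULL, T_grid = NULL,
                              V_ladder = seq(-120, 160, by = 20),
                              noise_sd = 0.02, n_replicates = 3L,
                              v_half_mod = 0, v_slope_mod = 40,
                              memory_Ea = 50e3, memory_T_ref = 298.15,
                              heteroscedastic = FALSE, seed = 1L) {
  name <- match.arg(name)
  stopifnot(noise_sd >= 0, v_slope_mod > 0, n_replicates >= 1)
  if (name == "trpv1_like") {
    if (is.null(thermo))
      thermo <- thermo_params(dH = 200e3, dS = 635,
                              dG_barrier_o = 30e3, dG_barrier_c = 26e3,
                              beta_o = 0.005, beta_c = 0.005)
    if (is.null(T_grid)) T_grid <- seq(296, 331, by = 5)
    if (!(thermo$dH > 0 && thermo$dS > 0))
      stop("trpv1_like requires dH > 0 and dS > 0 (heat activation)",
           call. = FALSE)
  } else if (name == "trpm8_like") {
    if (is.null(thermo))
      thermo <- thermo_params(dH = -150e3, dS = -520,
                              dG_barrier_o = 26e3, dG_barrier_c = 30e3,
                              beta_o = 0.005, beta_c = 0.005)
    if (is.null(T_grid)) T_grid <- seq(273, 308, by = 5)
    if (!(thermo$dH < 0 && thermo$dS < 0))
      stop("trpm8_like requires dH < 0 and dS < 0 (cold activation)",
           call. = FALSE)
  } else {
    if (is.null(thermo) || is.null(T_grid))
      stop("custom profiles need explicit thermo and T_grid",
           call. = FALSE)
  }
  if (length(T_grid) == 0 || length(V_ladder) == 0)
    stop("T_grid and V_ladder must be non-empty", call. = FALSE)
  structure(list(name = name, thermo = thermo, T_grid = T_grid,
                 V_ladder = V_ladder, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 v_half_mod = v_half_mod, v_slope_mod = v_slope_mod,
                 memory_Ea = memory_Ea, memory_T_ref = memory_T_ref,
                 heteroscedastic = heteroscedastic,
                 seed = as.integer(seed)),
            class = "generator_profile")
}

# multiplicative Boltzmann voltage factor
.voltage_factor <- function(V, v_half, v_slope) {
  1 / (1 + exp((v_half - V) / v_slope))
}

# noiseless open-probability surface of a profile
.profile_p_open <- function(profile, T_K) {
  th <- profile$thermo
  epsilon <- epsilon_with_memory(th$dH, th$dS, T_K,
                                 m_ref = th$k_c1 * th$tau_r,
                                 Ea_m = profile$memory_Ea,
                                 T_ref = profile$memory_T_ref)
  equilibrium_open_probability(epsilon, T_K)
}

#' Generate a synthetic G-T-V dataset
#'
#' The noiseless surface is
#' \eqn{g(T, V) = P_O(T)\, f_V(V)} with \eqn{P_O} the equilibrium open
#' probability from the profile's thermodynamics (including the memory
#' correction when present) and \eqn{f_V} a multiplicative Boltzmann
#' voltage factor.  Truncated-Gaussian noise is added (values clipped to
#' [0, 1]).  Every generating parameter and the seed are recorded in the
#' `generator` attribute, and regeneration from the same profile is
#' bitwise identical.
#'
#' @param profile a [generator_profile()].
#' @return A `gv_dataset` data frame with columns `temperature_K`,
#'   `voltage_mV`, `replicate`, `g_norm`, `sd`.
#' @examples
#' d <- generate_gv_dataset(generator_profile("trpv1_like", seed = 7))
#' head(d)
#' @export
generate_gv_dataset <- function(profile) {
  stopifnot(inherits(profile, "generator_profile"))
  grid <- expand.grid(replicate = seq_len(profile$n_replicates),
                      voltage_mV = profile$V_ladder,
                      temperature_K = profile$T_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[c("temperature_K", "voltage_mV", "replicate")]
  p <- .profile_p_open(profile, grid$temperature_K)
  fv <- .voltage_factor(grid$voltage_mV, profile$v_half_mod,
                        profile$v_slope_mod)
  g0 <- p * fv
  sd_vec <- if (profile$heteroscedastic)
    profile$noise_sd * 4 * g0 * (1 - g0) else
    rep(profile$noise_sd, length(g0))
  set.seed(profile$seed)
  g <- pmin(pmax(g0 + stats::rnorm(length(g0), 0, sd_vec), 0), 1)
  out <- data.frame(temperature_K = grid$temperature_K,
                    voltage_mV = grid$voltage_mV,
                    replicate = grid$replicate,
                    g_norm = g, sd = sd_vec)
  attr(out, "generator") <- unclass(profile)
  class(out) <- c("gv_dataset", "data.frame")
  out
}

#' Generate a dwell-time event list from a gating scheme
#'
#' Draws exactly `n_events` successive residence times along the scheme's
#' chain (a synthetic stand-in for an idealised single-channel recording),
#' reproducibly for a given seed.
#'
#' @param scheme a [gating_scheme()].
#' @param n_events number of dwells (>= 1).
#' @param seed integer seed.
#' @param start_state initial state (default: the first state of the
#'   chain).
#' @return Event data frame with columns `state` and `duration_s`.
#' @export
generate_dwell_events <- function(scheme, n_events, seed = 1,
                                  start_state = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"), n_events >= 1)
  if (is.null(start_state)) start_state <- scheme$states$label[1]
  if (!start_state %in% scheme$states$label)
    stop("unknown start_state '", start_state, "'", call. = FALSE)
  set.seed(seed)
  n_events <- as.integer(n_events)
  if (scheme$topology == "two_state") {
    other <- setdiff(c("C", "O"), start_state)
    states <- rep(c(start_state, other), length.out = n_events)
    nA <- sum(states == start_state); nB <- n_events - nA
    dA <- sample_dwell(scheme$dwell_laws[[start_state]], nA)
    dB <- if (nB > 0) sample_dwell(scheme$dwell_laws[[other]], nB)
          else numeric(0)
    durs <- numeric(n_events)
    durs[states == start_state] <- dA
    durs[states == other] <- dB
  } else {
    states <- character(n_events); durs <- numeric(n_events)
    s <- start_state
    for (i in seq_len(n_events)) {
      states[i] <- s
      durs[i] <- sample_dwell(scheme$dwell_laws[[s]], 1L)
      u <- if (s == "C2") stats::runif(1) else 0
      s <- .next_state(scheme, s, u)
    }
  }
  data.frame(state = states, duration_s = durs, stringsAsFactors = FALSE)
}

#' Collapse a multi-state event list to conductance classes
#'
#' An experimental record only distinguishes conducting from
#' non-conducting levels: successive sojourns in closed states (`C1`,
#' `C2`) merge into single closed (`C`) dwells.  This is how the memory of
#' a hidden closed stage shows up as a non-exponential closed residence
#' distribution in the observed record.
#'
#' @param events event data frame (`state`, `duration_s`), or a
#'   `gating_trajectory`.
#' @return Event data frame with states `C` and `O` only.
#' @export
collapse_to_conductance_events <- function(events) {
  ev <- .as_event_frame(events)
  cls <- ifelse(ev$state == "O", "O", "C")
  run_id <- cumsum(c(1L, as.integer(cls[-1] != cls[-length(cls)])))
  agg <- stats::aggregate(ev$duration_s, by = list(run = run_id), sum)
  data.frame(state = cls[!duplicated(run_id)], duration_s = agg$x,
             stringsAsFactors = FALSE)
}
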