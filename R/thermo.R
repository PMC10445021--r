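#' Thermodynamic gating parameters
#'
#' Container for the thermodynamic quantities entering the Eyring rate law
#' and the gating free-energy asymmetry.  All energies are molar (J/mol);
#' see [gating_constants()] for the per-molecule conversion.
#'
#' @param dH enthalpy difference \eqn{\Delta H = H_O - H_C} (J/mol).
#' @param dS entropy difference \eqn{\Delta S = S_O - S_C} (J/(mol K)).
#' @param dG_barrier_o,dG_barrier_c static free-energy barriers
#'   \eqn{\Delta G_{O}(V_0)}, \eqn{\Delta G_{C}(V_0)} (J/mol, >= 0) for the
#'   opening and closing transitions at the holding voltage.
#' @param nu0 attempt frequency \eqn{\nu_0} (1/s, > 0); kept fixed during
#'   fitting to avoid the barrier/prefactor degeneracy.
#' @param beta_o,beta_c voltage sensitivities
#'   \eqn{\beta_{o,c} = -d\ln k_{o,c}(0)/dV} (1/mV).
#' @param V0 static holding voltage (mV).
#' @param k_c1 closed-state-1 exit rate (1/s, >= 0); together with `tau_r`
#'   it sets the memory correction \eqn{RT\ln(1 + k_{c1}\tau_r)}.
#' @param tau_r memory/relaxation time \eqn{\tau_r} (s, >= 0).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params(dH = 200e3, dS = 635, dG_barrier_o = 30e3,
#'               dG_barrier_c = 26e3)
#' @export
thermo_params <- function(dH = 0, dS = 0,
                          dG_barrier_o = 0, dG_barrier_c = 0,
                          nu0 = 1e6, beta_o = 0, beta_c = 0, V0 = 0,
                          k_c1 = 0, tau_r = 0) {
  stopifnot(nu0 > 0, tau_r >= 0, k_c1 >= 0,
            dG_barrier_o >= 0, dG_barrier_c >= 0)
  structure(list(dH = dH, dS = dS,
                 dG_barrier_o = dG_barrier_o, dG_barrier_c = dG_barrier_c,
                 nu0 = nu0, beta_o = beta_o, beta_c = beta_c, V0 = V0,
                 k_c1 = k_c1, tau_r = tau_r),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  dH = %g J/mol, dS = %g J/(mol K)\n", x$dH, x$dS))
  cat(sprintf("  barriers: dG_o = %g, dG_c = %g J/mol; nu0 = %g /s\n",
              x$dG_barrier_o, x$dG_barrier_c, x$nu0))
  cat(sprintf("  beta_o = %g, beta_c = %g /mV at V0 = %g mV\n",
              x$beta_o, x$beta_c, x$V0))
  cat(sprintf("  memory: k_c1 = %g /s, tau_r = %g s (k_c1*tau_r = %g)\n",
              x$k_c1, x$tau_r, x$k_c1 * x$tau_r))
  invisible(x)
}

.check_T <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be positive (kelvin)", call. = FALSE)
}

#' Eyring rate constant at temperature T
#'
#' \eqn{k_{o,c}(0) = \nu_0 \exp[-\Delta G_{O,C}(V_0) / RT]} with the static
#' barrier for the requested transition direction.
#'
#' @param thermo a [thermo_params()].
#' @param which `"open_transition"` (barrier `dG_barrier_o`) or
#'   `"close_transition"` (barrier `dG_barrier_c`).
#' @param T absolute temperature(s) in kelvin (> 0).
#' @return Rate(s) in 1/s.
#' @examples
#' th <- thermo_params(dG_barrier_o = 50e3, nu0 = 1e9)
#' rate_constant(th, "open_transition", 310)
#' @export
rate_constant <- function(thermo,
                          which = c("open_transition", "close_transition"),
                          T) {
  which <- match.arg(which)
  .check_T(T)
  dG <- if (which == "open_transition") thermo$dG_barrier_o
        else thermo$dG_barrier_c
  thermo$nu0 * exp(-dG / (.R_GAS * T))
}

#' First-order voltage-driven rate
#'
#' The linearised driving \eqn{k(t) \approx k(0)(1 - \beta V_s(t))} for a
#' small voltage signal around the holding potential.  Values that the
#' linearisation would take negative are clamped to zero with a warning,
#' since a negative rate is unphysical (the first-order expansion is only
#' valid for small drivings).
#'
#' @param k0 undriven rate \eqn{k(0)} (1/s, > 0).
#' @param beta voltage sensitivity (1/mV).
#' @param Vs_t voltage signal \eqn{V_s(t)} (mV).
#' @return Driven rate(s) in 1/s, clamped at 0.
#' @examples
#' linearized_rate(100, 0.01, 50)  # 50
#' @export
linearized_rate <- function(k0, beta, Vs_t) {
  stopifnot(all(k0 > 0))
  k <- k0 * (1 - beta * Vs_t)
  if (any(k < 0)) {
    warning("linearized rate clamped at 0 (driving outside the ",
            "first-order regime)", call. = FALSE)
    k <- pmax(k, 0)
  }
  k
}

#' Gating free-energy asymmetry epsilon(T)
#'
#' \deqn{\varepsilon(T) = \Delta G_O(V_0) - \Delta G_C(V_0)
#'       + RT\ln(1 + k_{c1}\tau_r)}
#' (barrier form), or equivalently
#' \deqn{\varepsilon(T) = \Delta H - T\Delta S + RT\ln(1 + k_{c1}\tau_r)}
#' (enthalpy form); the two agree when
#' \eqn{\Delta G_O - \Delta G_C = \Delta H - T\Delta S}.  Sign convention:
#' `epsilon > 0` favours the closed state (open probability below 0.5).
#' The memory correction \eqn{RT\ln(1+k_{c1}\tau_r)} uses the constant
#' `k_c1` and `tau_r` stored in `thermo`; see [epsilon_with_memory()] for
#' the temperature-coupled memory rate used by the synthetic generator and
#' the non-Markov equilibrium fits.
#'
#' @param thermo a [thermo_params()].
#' @param T absolute temperature(s) in kelvin (> 0).
#' @param form `"enthalpy"` or `"barrier"`.
#' @return Energy (J/mol), same length as `T`.
#' @examples
#' th <- thermo_params(dH = 100e3, dS = 300)
#' epsilon_T(th, 320)  # 4000 J/mol
#' @export
epsilon_T <- function(thermo, T, form = c("enthalpy", "barrier")) {
  form <- match.arg(form)
  .check_T(T)
  m <- thermo$k_c1 * thermo$tau_r
  if (1 + m <= 0) stop("1 + k_c1*tau_r must be positive", call. = FALSE)
  memory <- .R_GAS * T * log1p(m)
  base <- if (form == "enthalpy") thermo$dH - T * thermo$dS
          else thermo$dG_barrier_o - thermo$dG_barrier_c
  base + memory
}

#' Epsilon(T) with an Eyring-coupled memory rate
#'
#' Generalises [epsilon_T()] by letting the memory product
#' \eqn{m(T) = k_{c1}(T)\tau_r} follow an Arrhenius/Eyring temperature
#' dependence around a reference temperature:
#' \deqn{m(T) = m_{ref}\exp[-E_a/R\,(1/T - 1/T_{ref})].}
#' With `Ea_m = 0` this reduces to the constant-memory form of
#' [epsilon_T()].  `m_ref` is the value of \eqn{k_{c1}\tau_r} at `T_ref`.
#'
#' @param dH,dS enthalpy (J/mol) and entropy (J/(mol K)) differences.
#' @param T absolute temperature(s) in kelvin.
#' @param m_ref memory product \eqn{k_{c1}\tau_r} at the reference
#'   temperature (>= 0).
#' @param Ea_m activation energy of the memory rate `k_c1` (J/mol).
#' @param T_ref reference temperature (K); default 298.15.
#' @return Energy (J/mol).
#' @export
epsilon_with_memory <- function(dH, dS, T, m_ref = 0, Ea_m = 0,
                                T_ref = 298.15) {
  .check_T(T)
  stopifnot(m_ref >= 0)
  m <- m_ref * exp(-Ea_m / .R_GAS * (1 / T - 1 / T_ref))
  dH - T * dS + .R_GAS * T * log1p(m)
}

#' Equilibrium open probability from the gating asymmetry
#'
#' Boltzmann mapping \eqn{P_O = 1/(1 + e^{\varepsilon/RT})}: equals 0.5 at
#' `eps = 0`, decreases monotonically in `eps`, and tends to 1 (0) as
#' `eps` tends to minus (plus) infinity.
#'
#' @param eps gating asymmetry \eqn{\varepsilon} (J/mol).
#' @param T absolute temperature(s) in kelvin (> 0).
#' @return Open probability in (0, 1).
#' @examples
#' equilibrium_open_probability(0, 310)  # 0.5
#' @export
equilibrium_open_probability <- function(eps, T) {
  .check_T(T)
  stats::plogis(-eps / (.R_GAS * T))
}

#' Half-activation temperature
#'
#' Temperature at which the open probability crosses 0.5; equals
#' \eqn{\Delta H / \Delta S} when the memory term vanishes.  Returns `NA`
#' with a message when `dS` is (numerically) zero, in which case no
#' half-activation temperature exists.
#'
#' @param thermo a [thermo_params()].
#' @return Temperature in kelvin, or `NA_real_`.
#' @export
half_activation_temperature <- function(thermo) {
  if (abs(thermo$dS) < .Machine$double.eps * 100) {
    message("dS = 0: half-activation temperature undefined")
    return(NA_real_)
  }
  m <- thermo$k_c1 * thermo$tau_r
  thermo$dH / (thermo$dS - .R_GAS * log1p(m))
}
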