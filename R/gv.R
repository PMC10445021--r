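# Conductance-voltage (G-V) and conductance-temperature (G-T) analysis:
# Boltzmann fits of the voltage dependence, van't Hoff extraction of dH/dS
# from the temperature dependence, and the Q10 thermosensitivity index.

#' Conductance from plateau current
#'
#' \eqn{G = I/(V - E_{rev})} in nS for current in pA and voltage in mV.
#' Records at the reversal potential are flagged and excluded (`NA`), not
#' divided.  The default `E_rev = 0` mV corresponds to symmetric-Na+
#' recording solutions.
#'
#' @param I_pA current(s) in pA.
#' @param V_mV voltage(s) in mV.
#' @param E_rev reversal potential (mV).
#' @return Conductance(s) in nS; `NA` (with a warning) where
#'   `V_mV == E_rev`.
#' @examples
#' conductance_from_current(160, 160)  # 1 nS
#' @export
conductance_from_current <- function(I_pA, V_mV, E_rev = 0) {
  bad <- V_mV == E_rev
  g <- ifelse(bad, NA_real_, I_pA / (V_mV - E_rev))
  if (any(bad))
    warning(sum(bad), " record(s) at the reversal potential excluded",
            call. = FALSE)
  g
}

#' Boltzmann fit of a G-V curve at fixed temperature
#'
#' Least-squares fit of \eqn{g = g_{max} / (1 + \exp[(V_{1/2} - V)/k])}
#' with half-activation voltage \eqn{V_{1/2}} and slope factor \eqn{k}
#' (both in mV), using Levenberg-Marquardt.  Needs at least 5 voltage
#' points spanning the transition; a flat curve (no voltage dependence) or
#' a non-converging fit yields an explicit failure report carrying the
#' residuals rather than spurious parameters.
#'
#' @param V_mV voltages (mV).
#' @param g conductances (normalised or raw, same units as `g_max`).
#' @return An object of class `boltzmann_fit`: list with `converged`,
#'   `estimate` (`V_half`, `slope`, `g_max`), `se`, `residuals`,
#'   `reason` (on failure).
#' @export
boltzmann_fit <- function(V_mV, g) {
  stopifnot(length(V_mV) == length(g))
  if (length(V_mV) < 5)
    stop("need at least 5 voltage points", call. = FALSE)
  fail <- function(reason) structure(
    list(converged = FALSE, reason = reason, estimate = NULL, se = NULL,
         residuals = g - mean(g)), class = "boltzmann_fit")
  if (diff(range(g)) < 1e-8 * max(abs(g), 1))
    return(fail("flat conductance: no voltage dependence to fit"))
  df <- data.frame(V = V_mV, g = g)
  v_half0 <- stats::approx(g, V_mV, xout = (max(g) + min(g)) / 2,
                           ties = mean)$y
  if (is.na(v_half0)) v_half0 <- stats::median(V_mV)
  start <- list(g_max = max(g), V_half = v_half0,
                slope = diff(range(V_mV)) / 6)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ g_max / (1 + exp((V_half - V) / slope)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("Levenberg-Marquardt did not converge"))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(converged = TRUE,
                 estimate = c(V_half = unname(est["V_half"]),
                              slope = unname(est["slope"]),
                              g_max = unname(est["g_max"])),
                 se = se, residuals = stats::resid(fit)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<boltzmann_fit> FAILED:", x$reason, "\n")
  } else {
    cat(sprintf("<boltzmann_fit> V_half = %.3g mV, slope = %.3g mV, g_max = %.3g\n",
                x$estimate["V_half"], x$estimate["slope"],
                x$estimate["g_max"]))
  }
  invisible(x)
}

#' Van't Hoff analysis of an activation curve
#'
#' Linear regression of \eqn{\ln K} on \eqn{1/T}, where
#' \eqn{K = p_{open}/(1 - p_{open})} is the open/closed equilibrium
#' constant: slope \eqn{= -\Delta H/R}, intercept \eqn{= \Delta S/R},
#' half-activation temperature \eqn{T^* = \Delta H/\Delta S} (undefined,
#' reported as `NA`, when \eqn{\Delta S = 0}).  Open probabilities at
#' exactly 0 or 1 are clipped to `[clip, 1 - clip]` with a warning before
#' taking logs; the induced bound on \eqn{\ln K} is
#' \eqn{\ln[(1-clip)/clip]}.  Ordinary (unweighted) least squares by
#' default; per-point weights may be supplied.
#'
#' @param T_K temperatures in kelvin (>= 4 points).
#' @param p_open open probabilities (or normalised conductances).
#' @param weights optional regression weights.
#' @param clip clipping bound for saturated probabilities (default 1e-6).
#' @return An object of class `vant_hoff_fit`: list with `dH` (J/mol),
#'   `dS` (J/(mol K)), `T_star` (K), `ci` (95\% intervals for dH and dS),
#'   `r_squared` and the underlying `lm` fit.
#' @examples
#' T_K <- seq(296, 331, 5)
#' p <- equilibrium_open_probability(
#'   epsilon_T(thermo_params(dH = 2e5, dS = 635), T_K), T_K)
#' vant_hoff_fit(T_K, p)
#' @export
vant_hoff_fit <- function(T_K, p_open, weights = NULL, clip = 1e-6) {
  .check_T(T_K)
  stopifnot(length(T_K) == length(p_open))
  if (length(T_K) < 4)
    stop("need at least 4 temperatures", call. = FALSE)
  if (any(p_open <= 0 | p_open >= 1)) {
    warning("p_open at or beyond [0, 1] clipped to [", clip, ", ",
            1 - clip, "]", call. = FALSE)
  }
  p <- pmin(pmax(p_open, clip), 1 - clip)
  lnK <- log(p / (1 - p))
  inv_T <- 1 / T_K
  fit <- if (is.null(weights)) stats::lm(lnK ~ inv_T)
         else stats::lm(lnK ~ inv_T, weights = weights)
  cf <- stats::coef(fit)
  dH <- -cf[["inv_T"]] * .R_GAS
  dS <- cf[["(Intercept)"]] * .R_GAS
  ci <- tryCatch(suppressMessages(stats::confint(fit)),
                 error = function(e) matrix(NA_real_, 2, 2))
  T_star <- if (abs(dS) < 1e-12) NA_real_ else dH / dS
  structure(list(dH = dH, dS = dS, T_star = T_star,
                 ci = list(dH = sort(-ci["inv_T", ] * .R_GAS),
                           dS = sort(ci["(Intercept)", ] * .R_GAS)),
                 r_squared = summary(fit)$r.squared, lm = fit),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("<vant_hoff_fit> dH = %.4g kJ/mol, dS = %.4g J/(mol K)",
              x$dH / 1e3, x$dS))
  if (is.na(x$T_star)) cat(", T* undefined (dS = 0)\n")
  else cat(sprintf(", T* = %.2f K (%.1f C)\n", x$T_star,
                   kelvin_to_celsius(x$T_star)))
  invisible(x)
}

#' Q10 thermosensitivity index
#'
#' Fold-change of a rate (or conductance) per 10 K:
#' \eqn{Q_{10} = (k_{T_2}/k_{T_1})^{10/(T_2 - T_1)}}.
#'
#' @param k_T1,k_T2 rates at `T1` and `T2` (> 0).
#' @param T1,T2 temperatures in kelvin (`T1 != T2`).
#' @return Dimensionless Q10.
#' @examples
#' q10(1, 2, 300, 310)  # 2
#' @export
q10 <- function(k_T1, k_T2, T1, T2) {
  stopifnot(all(k_T1 > 0), all(k_T2 > 0), all(T1 != T2))
  (k_T2 / k_T1)^(10 / (T2 - T1))
}

#' Conductance-temperature curve at a fixed voltage
#'
#' Extracts the records at the requested voltage (typically +80 or
#' +160 mV), averages replicates per temperature, and reports the
#' monotone trend by a Spearman rank test: heat-activated profiles are
#' non-decreasing in temperature (within noise), cold-activated profiles
#' non-increasing.
#'
#' @param dataset a `gv_dataset` (see [generate_gv_dataset()] /
#'   [read_gv_dataset()]).
#' @param V_mV voltage at which to extract the curve.
#' @return Data frame `temperature_K`, `g_mean`, `g_sd`, `n`; attributes
#'   `spearman_rho` and `spearman_p` when 3 or more temperatures are
#'   present.
#' @export
g_vs_temperature <- function(dataset, V_mV) {
  stopifnot(is.data.frame(dataset))
  volts <- sort(unique(dataset$voltage_mV))
  if (!any(abs(volts - V_mV) < 1e-9))
    stop("voltage ", V_mV, " mV not in the ladder; available: ",
         paste(volts, collapse = ", "), call. = FALSE)
  d <- dataset[abs(dataset$voltage_mV - V_mV) < 1e-9, , drop = FALSE]
  Ts <- sort(unique(d$temperature_K))
  out <- do.call(rbind, lapply(Ts, function(Tk) {
    g <- d$g_norm[d$temperature_K == Tk]
    data.frame(temperature_K = Tk, g_mean = mean(g),
               g_sd = stats::sd(g), n = length(g))
  }))
  if (nrow(out) >= 3) {
    ct <- suppressWarnings(
      stats::cor.test(out$temperature_K, out$g_mean, method = "spearman"))
    attr(out, "spearman_rho") <- unname(ct$estimate)
    attr(out, "spearman_p") <- ct$p.value
  }
  out
}

#' Normalise conductance records
#'
#' Divides conductances by the maximum either globally (default: one
#' scale for the whole dataset, preserving the relative amplitudes of
#' different temperatures) or per temperature (each G-V curve scaled to
#' its own maximum).
#'
#' @param dataset data frame with `temperature_K` and a conductance
#'   column `g` (or `g_norm`).
#' @param mode `"global"` or `"per_temperature"`.
#' @return The dataset with `g_norm` rescaled.
#' @export
normalize_conductance <- function(dataset,
                                  mode = c("global", "per_temperature")) {
  mode <- match.arg(mode)
  gcol <- if ("g_norm" %in% names(dataset)) "g_norm" else "g"
  g <- dataset[[gcol]]
  if (mode == "global") {
    dataset$g_norm <- g / max(g, na.rm = TRUE)
  } else {
    for (Tk in unique(dataset$temperature_K)) {
      i <- dataset$temperature_K == Tk
      dataset$g_norm[i] <- g[i] / max(g[i], na.rm = TRUE)
    }
  }
  dataset
}

#' Read / write G-T-V datasets as CSV
#'
#' Tables are comma-separated UTF-8 with a header; temperatures may be
#' given as `temperature_K` or `temperature_C` (converted on read), and
#' conductance either directly as `g_norm` or as `current_pA` (converted
#' via [conductance_from_current()] and globally normalised).
#'
#' @param path file path.
#' @param E_rev reversal potential for current-to-conductance conversion.
#' @return `read_gv_dataset` returns a `gv_dataset` data frame;
#'   `write_gv_dataset` returns `path` invisibly.
#' @export
read_gv_dataset <- function(path, E_rev = 0) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("temperature_C" %in% names(d) && !"temperature_K" %in% names(d))
    d$temperature_K <- celsius_to_kelvin(d$temperature_C)
  if (!all(c("temperature_K", "voltage_mV") %in% names(d)))
    stop("dataset needs temperature_K (or temperature_C) and voltage_mV",
         call. = FALSE)
  if (!"g_norm" %in% names(d)) {
    if (!"current_pA" %in% names(d))
      stop("dataset needs a g_norm or current_pA column", call. = FALSE)
    d$g <- conductance_from_current(d$current_pA, d$voltage_mV, E_rev)
    d <- d[!is.na(d$g), , drop = FALSE]
    d <- normalize_conductance(d, "global")
  }
  class(d) <- c("gv_dataset", "data.frame")
  d
}

#' @rdname read_gv_dataset
#' @param dataset a `gv_dataset` data frame.
#' @export
write_gv_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
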