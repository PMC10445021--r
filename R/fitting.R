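# Model fitting: identifiability accounting, equilibrium (G-T-V) fits,
# maximum-likelihood dwell-law fits, and AIC-based model comparison.

#' Parameter counting and identifiability cap per model
#'
#' For the three-state Markov chain, six rate coefficients define the
#' model but only four independent parameters are determinable from
#' recordings that distinguish just conducting and non-conducting levels;
#' the two-state Markov chain is fully determined by its two rates.
#' Non-Markov variants add one dwell-shape parameter per state on top of
#' the per-state mean rates: with gamma laws the two-state non-Markov
#' model has 4 raw coefficients (2 means + 2 shapes), all identifiable,
#' and the three-state variant has 9 raw coefficients of which 4 + 3
#' shapes = 7 are identifiable.
#'
#' @param model_tag one of `"markov_2"`, `"markov_3"`, `"nonmarkov_2"`,
#'   `"nonmarkov_3"`.
#' @return Named list `n_rate_coefficients`, `n_identifiable`.
#' @examples
#' count_parameters("markov_3")  # 6 coefficients, 4 identifiable
#' @export
count_parameters <- function(model_tag = c("markov_2", "markov_3",
                                           "nonmarkov_2", "nonmarkov_3")) {
  model_tag <- match.arg(model_tag)
  switch(model_tag,
    markov_2 = list(n_rate_coefficients = 2L, n_identifiable = 2L),
    markov_3 = list(n_rate_coefficients = 6L, n_identifiable = 4L),
    nonmarkov_2 = list(n_rate_coefficients = 4L, n_identifiable = 4L),
    nonmarkov_3 = list(n_rate_coefficients = 9L, n_identifiable = 7L))
}

.default_free <- function(model_tag) {
  if (model_tag %in% c("markov_2", "markov_3")) c("dH", "dS")
  else c("dH", "dS", "m_ref")
}

.data_fingerprint <- function(x) {
  num <- vapply(x, is.numeric, logical(1))
  c(n = nrow(x), sums = round(sum(vapply(x[num], sum, numeric(1))), 6))
}

#' Fit an equilibrium gating model to a G-T(-V) dataset
#'
#' Minimises the (optionally sd-weighted) squared deviation between the
#' observed normalised conductance and the model surface
#' \eqn{g(T, V) = P_O(T)\,f_V(V)\,g_{max}}, where for the two-state
#' models \eqn{P_O = 1/(1 + e^{\varepsilon(T)/RT})} and for the
#' three-state models \eqn{P_O = 1/(1 + (1 + c_{21})e^{\varepsilon/RT})}
#' with the closed-closed equilibrium ratio \eqn{c_{21}} fixed by
#' configuration (honouring the 6-vs-4 identifiability accounting rather
#' than pretending all rate coefficients are free).  For non-Markov tags
#' \eqn{\varepsilon(T)} carries the memory correction
#' \eqn{RT\ln(1 + m(T))} with \eqn{m(T)} Eyring-coupled around a
#' reference temperature ([epsilon_with_memory()]); the attempt frequency
#' is never free.
#'
#' Optimisation is multi-start Nelder-Mead (a van't Hoff warm start plus
#' seeded random restarts); the covariance comes from the numerical
#' Hessian of the chi-square surface at the optimum.  A residual runs
#' test (Wald-Wolfowitz on residual signs ordered by temperature) is
#' reported to flag systematic lack of fit of a misspecified model.
#'
#' @param dataset a `gv_dataset` data frame spanning at least 4
#'   temperatures.
#' @param model_tag model to fit (see [count_parameters()]).
#' @param config named list of options: `voltages` (subset of the ladder
#'   to fit; default all), `free` (character vector of free parameters
#'   among `"dH"`, `"dS"`, `"m_ref"`, `"g_max"`), `memory_Ea`, `T_ref`,
#'   `c21`, `n_starts` (default 8), `seed`, `use_sd_weights` (default
#'   `TRUE` when the dataset has an `sd` column), `v_half_mod`,
#'   `v_slope_mod` (voltage factor; defaults from the dataset's
#'   generator metadata when present).
#' @return An object of class `gating_fit` with elements `params`
#'   (fitted values), `se`, `ci` (95\%), `cov`, `loss`, `logLik`, `AIC`,
#'   `AICc`, `model_tag`, `n`, `k_free`, `residuals`, `runs_test_p`,
#'   `config`, `fingerprint`.
#' @export
fit_equilibrium_model <- function(dataset,
                                  model_tag = c("markov_2", "markov_3",
                                                "nonmarkov_2",
                                                "nonmarkov_3"),
                                  config = list()) {
  model_tag <- match.arg(model_tag)
  stopifnot(is.data.frame(dataset),
            all(c("temperature_K", "g_norm") %in% names(dataset)))
  gen <- attr(dataset, "generator")
  cfg <- utils::modifyList(list(
    voltages = NULL,
    free = .default_free(model_tag),
    memory_Ea = if (!is.null(gen)) gen$memory_Ea else 50e3,
    T_ref = if (!is.null(gen)) gen$memory_T_ref else 298.15,
    c21 = 1,
    n_starts = 8L,
    seed = 1L,
    use_sd_weights = "sd" %in% names(dataset),
    v_half_mod = if (!is.null(gen)) gen$v_half_mod else 0,
    v_slope_mod = if (!is.null(gen)) gen$v_slope_mod else 40
  ), config)

  if (!all(c("dH", "dS") %in% cfg$free))
    stop("free parameters must include dH and dS", call. = FALSE)
  bad <- setdiff(cfg$free, c("dH", "dS", "m_ref", "g_max"))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (model_tag %in% c("markov_2", "markov_3") && "m_ref" %in% cfg$free)
    stop("the memory parameter m_ref is not part of a Markov model",
         call. = FALSE)
  cap <- count_parameters(model_tag)$n_identifiable
  if (length(cfg$free) > cap)
    stop("refusing an under-determined configuration: ", length(cfg$free),
         " free parameters (", paste(cfg$free, collapse = ", "),
         ") exceed the identifiability cap of ", cap, " for ", model_tag,
         call. = FALSE)

  d <- as.data.frame(dataset)
  if (!is.null(cfg$voltages) && "voltage_mV" %in% names(d))
    d <- d[d$voltage_mV %in% cfg$voltages, , drop = FALSE]
  if (!"voltage_mV" %in% names(d)) d$voltage_mV <- NA_real_
  ord <- order(d$temperature_K, d$voltage_mV)
  d <- d[ord, , drop = FALSE]
  if (length(unique(d$temperature_K)) < 4)
    stop("dataset must span at least 4 temperatures", call. = FALSE)

  fv <- ifelse(is.na(d$voltage_mV), 1,
               .voltage_factor(d$voltage_mV, cfg$v_half_mod,
                               cfg$v_slope_mod))
  sd_w <- if (isTRUE(cfg$use_sd_weights) && "sd" %in% names(d) &&
              all(d$sd > 0)) d$sd else NULL
  three_state <- model_tag %in% c("markov_3", "nonmarkov_3")
  nonmarkov <- model_tag %in% c("nonmarkov_2", "nonmarkov_3")
  closed_mult <- if (three_state) 1 + cfg$c21 else 1

  free <- cfg$free
  # parameter vector on a scaled, unconstrained space:
  # dH / 1e5, dS / 1e2, sqrt(m_ref), log(g_max)
  predict_g <- function(th) {
    m <- if ("m_ref" %in% free) th[["m_ref"]] else 0
    eps <- epsilon_with_memory(th[["dH"]], th[["dS"]], d$temperature_K,
                               m_ref = m, Ea_m = cfg$memory_Ea,
                               T_ref = cfg$T_ref)
    p <- 1 / (1 + closed_mult * exp(eps / (.R_GAS * d$temperature_K)))
    gm <- if ("g_max" %in% free) th[["g_max"]] else 1
    p * fv * gm
  }
  unpack <- function(par) {
    th <- list(dH = par[1] * 1e5, dS = par[2] * 1e2)
    i <- 3
    if ("m_ref" %in% free) { th$m_ref <- par[i]^2; i <- i + 1 }
    if ("g_max" %in% free) { th$g_max <- exp(par[i]); i <- i + 1 }
    th
  }
  objective <- function(par) {
    r <- d$g_norm - predict_g(unpack(par))
    if (!is.null(sd_w)) sum((r / sd_w)^2) else sum(r^2)
  }

  # warm start: van't Hoff on voltage-corrected observations
  p_obs <- pmin(pmax(d$g_norm / fv / closed_mult, 1e-6), 1 - 1e-6)
  vh <- suppressWarnings(
    tryCatch(vant_hoff_fit(d$temperature_K, p_obs),
             error = function(e) NULL))
  base <- if (!is.null(vh)) c(vh$dH / 1e5, vh$dS / 1e2) else c(1, 3)
  starts <- list(c(base,
                   if ("m_ref" %in% free) 1 else NULL,
                   if ("g_max" %in% free) 0 else NULL))
  set.seed(cfg$seed)
  for (i in seq_len(max(cfg$n_starts - 1L, 0L))) {
    starts[[i + 1L]] <- c(base * stats::runif(2, 0.6, 1.4),
                          if ("m_ref" %in% free)
                            stats::runif(1, 0, sqrt(5)) else NULL,
                          if ("g_max" %in% free)
                            stats::runif(1, -0.2, 0.2) else NULL)
  }
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(stats::optim(s0, objective,
                               control = list(maxit = 3000,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  best <- stats::optim(best$par, objective,
                       control = list(maxit = 5000, reltol = 1e-14))

  n <- nrow(d)
  k_free <- length(free)
  th <- unpack(best$par)
  scale_jac <- c(1e5, 1e2,
                 if ("m_ref" %in% free) 2 * best$par[3] else NULL,
                 if ("g_max" %in% free)
                   exp(best$par[k_free]) else NULL)[seq_len(k_free)]
  H <- tryCatch(stats::optimHess(best$par, objective),
                error = function(e) NULL)
  cov_par <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (!is.null(sd_w)) {
    sigma2_hat <- NULL
    cov_scaled <- if (!is.null(cov_par)) 2 * cov_par else NULL
    crit <- stats::qnorm(0.975)
    ll <- -0.5 * best$value - sum(log(sd_w)) - n / 2 * log(2 * pi)
    k_eff <- k_free
  } else {
    sigma2_hat <- best$value / max(n - k_free, 1)
    cov_scaled <- if (!is.null(cov_par)) 2 * sigma2_hat * cov_par
                  else NULL
    crit <- stats::qt(0.975, df = max(n - k_free, 1))
    ll <- -n / 2 * (log(2 * pi * max(best$value, 1e-300) / n) + 1)
    k_eff <- k_free + 1  # residual variance estimated
  }
  cov_nat <- se <- ci <- NULL
  if (!is.null(cov_scaled) && all(is.finite(cov_scaled))) {
    cov_nat <- diag(scale_jac, k_free) %*% cov_scaled %*%
      diag(scale_jac, k_free)
    dimnames(cov_nat) <- list(free, free)
    se <- sqrt(pmax(diag(cov_nat), 0))
    ci <- cbind(lower = unlist(th)[free] - crit * se,
                upper = unlist(th)[free] + crit * se)
  }
  res <- d$g_norm - predict_g(th)
  aic <- -2 * ll + 2 * k_eff
  aicc <- aic + if (n / k_eff < 40 && n - k_eff - 1 > 0)
    2 * k_eff * (k_eff + 1) / (n - k_eff - 1) else 0
  structure(list(params = th, se = se, ci = ci, cov = cov_nat,
                 loss = best$value, logLik = ll, AIC = aic, AICc = aicc,
                 model_tag = model_tag, n = n, k_free = k_eff,
                 residuals = res,
                 runs_test_p = .runs_test_p(res),
                 sigma2_hat = sigma2_hat,
                 config = cfg,
                 fingerprint = .data_fingerprint(d),
                 convergence = best$convergence),
            class = "gating_fit")
}

#' @export
print.gating_fit <- function(x, ...) {
  cat("<gating_fit>", x$model_tag, "- n =", x$n, "records\n")
  cat("  params:", paste(names(x$params),
                         signif(unlist(x$params), 5),
                         sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  loss = %.6g, AICc = %.4g, runs-test p = %.3g\n",
              x$loss, x$AICc, x$runs_test_p))
  invisible(x)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation);
# returns 1 when all residuals share a sign (no run structure to test).
.runs_test_p <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 4) return(1)
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Maximum-likelihood dwell-law fits per state
#'
#' Fits the requested residence-time family to each state's completed
#' dwells.  Exponential, gamma and stretched-exponential (Weibull) laws
#' are fitted by `fitdistrplus::fitdist`; the Pareto law has the
#' closed-form MLE \eqn{\hat t_m = \min x},
#' \eqn{\hat\alpha = n / \sum\ln(x/\hat t_m)}.  Each per-state fit
#' reports the log-likelihood and the Kolmogorov-Smirnov distance between
#' the empirical and fitted CDFs.  Fewer events than `min_events` yields
#' a warning (wide confidence intervals), not a failure; an empty event
#' list is an error.
#'
#' @param events event data frame (`state`, `duration_s`), e.g. from
#'   [generate_dwell_events()] or [collapse_to_conductance_events()].
#' @param family dwell-law family to fit (see [dwell_law()]).
#' @param min_events floor for stable shape estimation (default 50).
#' @return A named list (one element per state) of class `dwell_fit_set`;
#'   each element has `law` (the fitted [dwell_law()]), `estimate`, `se`,
#'   `logLik`, `AIC`, `ks_distance`, `n`.
#' @export
fit_dwell_laws <- function(events,
                           family = c("exponential", "gamma",
                                      "stretched_exponential", "pareto"),
                           min_events = 50L) {
  family <- match.arg(family)
  ev <- .as_event_frame(events)
  if (!is.null(ev$truncated)) ev <- ev[!ev$truncated, , drop = FALSE]
  if (nrow(ev) == 0) stop("empty event list", call. = FALSE)
  states <- unique(ev$state)
  out <- lapply(states, function(s) {
    x <- ev$duration_s[ev$state == s]
    if (length(x) < min_events)
      warning("state ", s, ": only ", length(x), " events (< ",
              min_events, "); expect wide confidence intervals",
              call. = FALSE)
    .fit_one_dwell_law(x, family)
  })
  names(out) <- states
  structure(out, class = "dwell_fit_set", family = family,
            fingerprint = .data_fingerprint(ev))
}

.fit_one_dwell_law <- function(x, family) {
  n <- length(x)
  if (family == "pareto") {
    tmin <- min(x)
    alpha <- n / sum(log(x / tmin))
    ll <- n * log(alpha) + n * alpha * log(tmin) -
      (alpha + 1) * sum(log(x))
    law <- dwell_law("pareto", alpha = alpha, tmin = tmin)
    est <- c(alpha = alpha, tmin = tmin)
    se <- c(alpha = alpha / sqrt(n), tmin = NA_real_)
    k <- 2
  } else {
    dist <- switch(family, exponential = "exp", gamma = "gamma",
                   stretched_exponential = "weibull")
    fd <- fitdistrplus::fitdist(x, dist)
    est_raw <- fd$estimate
    se <- fd$sd
    ll <- stats::logLik(fd)[1]
    k <- length(est_raw)
    law <- switch(family,
      exponential = dwell_law("exponential",
                              rate = unname(est_raw["rate"])),
      gamma = dwell_law("gamma", shape = unname(est_raw["shape"]),
                        scale = 1 / unname(est_raw["rate"])),
      stretched_exponential = {
        b <- unname(est_raw["shape"])
        if (b > 1) {
          warning("fitted Weibull shape ", signif(b, 4), " > 1 lies ",
                  "outside the stretched-exponential regime; clamped ",
                  "to 1", call. = FALSE)
          b <- 1
        }
        dwell_law("stretched_exponential", stretch = b,
                  scale = unname(est_raw["scale"]))
      })
    est <- est_raw
  }
  xs <- sort(x)
  Fhat <- dwell_cdf(law, xs)
  ks <- max(abs(seq_len(n) / n - Fhat), abs((seq_len(n) - 1) / n - Fhat))
  list(law = law, estimate = est, se = se, logLik = ll,
       AIC = -2 * ll + 2 * k, ks_distance = ks, n = n)
}

#' Fit a full kinetic model to observed open/closed dwell lists
#'
#' The dwell-time route to model comparison: a `markov_2` model assigns
#' exponential residence laws to the observed closed and open classes; a
#' `nonmarkov_2` model assigns gamma laws (one extra shape parameter per
#' state), capturing the non-exponential closed residence produced by
#' hidden closed stages (the memory term).  The joint log-likelihood over
#' both states feeds AIC-based comparison via [compare_models()].
#'
#' @param events observed event data frame with states `C` and `O` (use
#'   [collapse_to_conductance_events()] for multi-state simulations).
#' @param model_tag `"markov_2"` or `"nonmarkov_2"`.
#' @param min_events per-state event floor (see [fit_dwell_laws()]).
#' @return An object of class `gating_fit` with the fitted per-state
#'   laws in `params`.
#' @export
fit_dwell_model <- function(events, model_tag = c("markov_2",
                                                  "nonmarkov_2"),
                            min_events = 50L) {
  model_tag <- match.arg(model_tag)
  ev <- .as_event_frame(events)
  if (!setequal(unique(ev$state), c("C", "O")))
    stop("expected observed events with states C and O; collapse ",
         "multi-state simulations first", call. = FALSE)
  family <- if (model_tag == "markov_2") "exponential" else "gamma"
  fits <- fit_dwell_laws(ev, family = family, min_events = min_events)
  ll <- sum(vapply(fits, function(f) f$logLik, numeric(1)))
  k <- sum(vapply(fits, function(f) length(f$estimate), numeric(1)))
  n <- nrow(ev)
  aic <- -2 * ll + 2 * k
  aicc <- aic + if (n / k < 40 && n - k - 1 > 0)
    2 * k * (k + 1) / (n - k - 1) else 0
  structure(list(params = lapply(fits, function(f) f$law),
                 per_state = fits, loss = -ll, logLik = ll, AIC = aic,
                 AICc = aicc, model_tag = model_tag, n = n, k_free = k,
                 fingerprint = attr(fits, "fingerprint")),
            class = "gating_fit")
}

#' Rank fitted models by AIC
#'
#' All fits must come from the identical dataset (checked by a data
#' fingerprint).  Models are ranked by AICc; the table reports
#' \eqn{\Delta AIC} relative to the best model and Akaike weights
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}.
#'
#' @param results list of `gating_fit` objects on the same dataset.
#' @return Data frame `model_tag`, `k_free`, `AICc`, `delta_AIC`,
#'   `akaike_weight`, sorted best first.
#' @export
compare_models <- function(results) {
  stopifnot(is.list(results), length(results) >= 1,
            all(vapply(results, inherits, logical(1), "gating_fit")))
  fps <- lapply(results, function(r) r$fingerprint)
  if (length(results) > 1 &&
      !all(vapply(fps[-1], identical, logical(1), fps[[1]])))
    stop("fits were not obtained on the identical dataset", call. = FALSE)
  tab <- data.frame(
    model_tag = vapply(results, function(r) r$model_tag, character(1)),
    k_free = vapply(results, function(r) r$k_free, numeric(1)),
    AICc = vapply(results, function(r) r$AICc, numeric(1)))
  tab$delta_AIC <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AIC / 2)
  tab$akaike_weight <- w / sum(w)
  tab[order(tab$AICc), , drop = FALSE]
}
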