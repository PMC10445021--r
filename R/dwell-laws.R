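#' Residence-time (dwell) distribution families
#'
#' A `dwell_law` describes the distribution of the residence time spent in a
#' kinetic state before the next transition.  The exponential family gives the
#' memoryless (Markov) limit; gamma and stretched-exponential laws realise a
#' "broad distribution of rates" with finite mean; the Pareto power law gives
#' heavy tails whose mean is infinite for tail exponent `alpha <= 1`.
#'
#' Parameterisations:
#' \describe{
#'   \item{`exponential`}{`rate` \eqn{\lambda} (1/s); density
#'     \eqn{\lambda e^{-\lambda t}}.}
#'   \item{`gamma`}{`shape` \eqn{\kappa} and `scale` \eqn{\theta_s} (s);
#'     mean \eqn{\kappa\theta_s}.}
#'   \item{`stretched_exponential`}{`stretch` \eqn{b \in (0, 1]} and `scale`
#'     \eqn{\theta_s} (s); survival \eqn{\exp[-(t/\theta_s)^b]} (a Weibull
#'     law with shape at most 1).}
#'   \item{`pareto`}{tail exponent `alpha` (> 0) and lower cut-off `tmin`
#'     (s); survival \eqn{(t_m/t)^\alpha} for \eqn{t \ge t_m}.}
#' }
#'
#' @param family one of `"exponential"`, `"gamma"`,
#'   `"stretched_exponential"`, `"pareto"`.
#' @param rate exponential rate \eqn{\lambda} (1/s).
#' @param shape gamma shape \eqn{\kappa}.
#' @param scale gamma or stretched-exponential scale \eqn{\theta_s} (s).
#' @param stretch stretch exponent \eqn{b \in (0, 1]}.
#' @param alpha Pareto tail exponent (> 0).
#' @param tmin Pareto lower cut-off \eqn{t_m} (s, > 0).
#' @return An object of class `dwell_law`.
#' @examples
#' dwell_law("exponential", rate = 2)
#' dwell_law("gamma", shape = 2, scale = 0.1)
#' dwell_law("pareto", alpha = 0.5, tmin = 0.01)
#' @export
dwell_law <- function(family = c("exponential", "gamma",
                                 "stretched_exponential", "pareto"),
                      rate = NULL, shape = NULL, scale = NULL,
                      stretch = NULL, alpha = NULL, tmin = NULL) {
  family <- match.arg(family)
  params <- switch(family,
    exponential = {
      stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
      list(rate = rate)
    },
    gamma = {
      stopifnot(is.numeric(shape), shape > 0, is.numeric(scale), scale > 0)
      list(shape = shape, scale = scale)
    },
    stretched_exponential = {
      stopifnot(is.numeric(stretch), stretch > 0, stretch <= 1,
                is.numeric(scale), scale > 0)
      list(stretch = stretch, scale = scale)
    },
    pareto = {
      stopifnot(is.numeric(alpha), alpha > 0, is.numeric(tmin), tmin > 0)
      list(alpha = alpha, tmin = tmin)
    })
  structure(list(family = family, params = params), class = "dwell_law")
}

#' @export
print.dwell_law <- function(x, ...) {
  cat("<dwell_law>", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      ")\n")
  invisible(x)
}

.check_dwell_t <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("dwell times must be finite and non-negative", call. = FALSE)
}

#' Density, CDF, survival, hazard, quantile and mean of a dwell law
#'
#' `dwell_survival(law, t)` is \eqn{\Phi(t) = 1 - F(t)}, the probability that
#' the state has not yet been left at time `t`; `dwell_hazard(law, t)` is the
#' instantaneous transition rate \eqn{\psi(t)/\Phi(t)}, constant only for the
#' exponential family -- its time dependence is the signature of
#' non-Markovian gating.  `dwell_mean` returns `Inf` (an explicit
#' infinite-mean signal, not an overflow) for a Pareto law with
#' `alpha <= 1`.
#'
#' @param law a [dwell_law()].
#' @param t non-negative time(s) in seconds.
#' @param p probability (for `dwell_quantile`).
#' @return Numeric vector (density in 1/s, probabilities, quantiles in s) or
#'   a single mean in s.
#' @examples
#' law <- dwell_law("exponential", rate = 2)
#' dwell_density(law, 0.5)
#' dwell_survival(law, 0)        # 1
#' dwell_mean(law)               # 0.5
#' dwell_mean(dwell_law("pareto", alpha = 0.5, tmin = 0.01))  # Inf
#' @export
dwell_density <- function(law, t) {
  .check_dwell_t(t)
  p <- law$params
  switch(law$family,
    exponential = stats::dexp(t, rate = p$rate),
    gamma = stats::dgamma(t, shape = p$shape, scale = p$scale),
    stretched_exponential = stats::dweibull(t, shape = p$stretch,
                                            scale = p$scale),
    pareto = ifelse(t < p$tmin, 0,
                    p$alpha * p$tmin^p$alpha / t^(p$alpha + 1)))
}

#' @rdname dwell_density
#' @export
dwell_cdf <- function(law, t) {
  .check_dwell_t(t)
  p <- law$params
  switch(law$family,
    exponential = stats::pexp(t, rate = p$rate),
    gamma = stats::pgamma(t, shape = p$shape, scale = p$scale),
    stretched_exponential = stats::pweibull(t, shape = p$stretch,
                                            scale = p$scale),
    pareto = ifelse(t < p$tmin, 0, 1 - (p$tmin / t)^p$alpha))
}

#' @rdname dwell_density
#' @export
dwell_survival <- function(law, t) {
  .check_dwell_t(t)
  p <- law$params
  switch(law$family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    gamma = stats::pgamma(t, shape = p$shape, scale = p$scale,
                          lower.tail = FALSE),
    stretched_exponential = stats::pweibull(t, shape = p$stretch,
                                            scale = p$scale,
                                            lower.tail = FALSE),
    pareto = ifelse(t < p$tmin, 1, (p$tmin / t)^p$alpha))
}

#' @rdname dwell_density
#' @export
dwell_hazard <- function(law, t) {
  .check_dwell_t(t)
  surv <- dwell_survival(law, t)
  if (any(surv <= 0))
    stop("survival underflow: hazard undefined where Phi(t) = 0",
         call. = FALSE)
  dwell_density(law, t) / surv
}

#' @rdname dwell_density
#' @export
dwell_quantile <- function(law, p) {
  stopifnot(all(p >= 0), all(p <= 1))
  pa <- law$params
  switch(law$family,
    exponential = stats::qexp(p, rate = pa$rate),
    gamma = stats::qgamma(p, shape = pa$shape, scale = pa$scale),
    stretched_exponential = stats::qweibull(p, shape = pa$stretch,
                                            scale = pa$scale),
    pareto = pa$tmin * (1 - p)^(-1 / pa$alpha))
}

#' @rdname dwell_density
#' @export
dwell_mean <- function(law) {
  p <- law$params
  switch(law$family,
    exponential = 1 / p$rate,
    gamma = p$shape * p$scale,
    stretched_exponential = p$scale * gamma(1 + 1 / p$stretch),
    pareto = if (p$alpha <= 1) Inf else p$alpha * p$tmin / (p$alpha - 1))
}

#' Laplace transform of a dwell-time density
#'
#' \eqn{\hat\psi(s) = \int_0^\infty e^{-st}\psi(t)\,dt}, with
#' \eqn{\hat\psi(0) = 1} for every proper law.  Exponential and gamma laws
#' have closed forms valid for complex `s` with non-negative real part (as
#' required by the Laplace-domain master equation and its numerical
#' inversion); stretched-exponential and Pareto transforms are computed by
#' adaptive quadrature and support real `s >= 0` only.
#'
#' @param law a [dwell_law()].
#' @param s Laplace variable (1/s); real non-negative, or complex with
#'   non-negative real part for exponential/gamma laws.
#' @return \eqn{\hat\psi(s)}, same length as `s`.
#' @examples
#' dwell_laplace(dwell_law("exponential", rate = 2), 1)   # 2/3
#' dwell_laplace(dwell_law("gamma", shape = 2, scale = 1), 1)  # 1/4
#' @export
dwell_laplace <- function(law, s) {
  p <- law$params
  if (is.complex(s)) {
    if (any(Re(s) < 0)) stop("Re(s) must be non-negative", call. = FALSE)
    return(switch(law$family,
      exponential = p$rate / (p$rate + s),
      gamma = exp(-p$shape * log(1 + p$scale * s)),
      stop("complex-argument Laplace transform is available only for ",
           "exponential and gamma dwell laws", call. = FALSE)))
  }
  if (any(!is.finite(s)) || any(s < 0))
    stop("s must be finite and non-negative", call. = FALSE)
  switch(law$family,
    exponential = p$rate / (p$rate + s),
    gamma = (1 + p$scale * s)^(-p$shape),
    stretched_exponential = vapply(s, function(si) {
      # substitution u = (t / scale)^b removes the t -> 0 singularity
      stats::integrate(function(u)
        exp(-u - si * p$scale * u^(1 / p$stretch)),
        lower = 0, upper = Inf, rel.tol = 1e-12,
        subdivisions = 500L)$value
    }, numeric(1)),
    pareto = vapply(s, function(si) {
      if (si == 0) return(1)
      stats::integrate(function(t) exp(-si * t) * dwell_density(law, t),
                       lower = p$tmin, upper = Inf, rel.tol = 1e-10,
                       subdivisions = 500L)$value
    }, numeric(1)))
}

#' Draw dwell times by inverse-CDF sampling
#'
#' Uses the quantile function applied to `runif`, so a fixed RNG state maps
#' deterministically to the sampled dwells.
#'
#' @param law a [dwell_law()].
#' @param n number of dwells to draw.
#' @return Numeric vector of `n` positive dwell times (s).
#' @export
sample_dwell <- function(law, n) {
  dwell_quantile(law, stats::runif(n))
}

#' Rescale a dwell law to a prescribed mean
#'
#' Temperature enters non-exponential dwell laws by rescaling the law's time
#' scale so that its mean equals the reciprocal of the Eyring rate at that
#' temperature, leaving shape parameters fixed (minimal coupling).  A Pareto
#' law must have a finite mean (`alpha > 1`) to be rescaled.
#'
#' @param law a [dwell_law()].
#' @param mean target mean residence time (s, > 0).
#' @return A new `dwell_law` of the same family with the requested mean.
#' @export
dwell_rescale_mean <- function(law, mean) {
  stopifnot(is.numeric(mean), mean > 0)
  p <- law$params
  switch(law$family,
    exponential = dwell_law("exponential", rate = 1 / mean),
    gamma = dwell_law("gamma", shape = p$shape, scale = mean / p$shape),
    stretched_exponential = dwell_law("stretched_exponential",
                                      stretch = p$stretch,
                                      scale = mean / gamma(1 + 1 / p$stretch)),
    pareto = {
      if (p$alpha <= 1)
        stop("cannot rescale a Pareto law with infinite mean (alpha <= 1)",
             call. = FALSE)
      dwell_law("pareto", alpha = p$alpha,
                tmin = mean * (p$alpha - 1) / p$alpha)
    })
}
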