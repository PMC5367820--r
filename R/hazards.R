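# Closed-form MSCE hazards. All exponentials are kept <= 1 by factoring out
# exp(-p t) (the growing one, p < 0), so no overflow occurs for |p| t up to
# many hundreds of years.

# log of the base ratio B(t) = (q - p) e^{p t} / (q - p e^{(p-q)t}), which
# lies in (0, 1] for t >= 0 and equals 1 at t = 0.
.log_base_ratio <- function(t, p, q) {
  E <- exp((p - q) * t)                 # <= 1
  pmin(log(q - p) + p * t - log(q - p * E), 0)  # B <= 1 analytically
}

.check_hazard_args <- function(t, pq) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (!is.finite(pq$p) || !is.finite(pq$q) || pq$p > 0 || pq$q < 0)
    stop("pq must satisfy p <= 0 <= q")
}

#' Two-stage clonal expansion hazard
#'
#' \deqn{h_2(t) = r_2 \, p q (e^{-qt} - e^{-pt}) / (q e^{-pt} - p e^{-qt})}
#' with \eqn{r_2 = \nu X / \alpha}. Starts at 0, rises through exponential
#' and linear phases, and saturates at the asymptote \eqn{-p\, r_2}.
#'
#' @param t age in years (vectorized, >= 0).
#' @param r2 the identifiable prefactor \eqn{\nu X/\alpha} (> 0).
#' @param pq a [compute_pq()] pair.
#' @return hazard per person-year, same length as `t`.
#' @examples
#' pq <- compute_pq(9, 8.7, 1e-5)
#' hazard_2(c(0, 40, 80), r2 = 0.015, pq = pq)
#' @export
hazard_2 <- function(t, r2, pq) {
  .check_hazard_args(t, pq)
  if (!is.finite(r2) || r2 <= 0) stop("r2 must be > 0")
  p <- pq$p; q <- pq$q
  E <- exp((p - q) * t)
  h <- r2 * p * q * (E - 1) / (q - p * E)
  if (any(is.nan(h))) stop("hazard_2 produced NaN")
  h
}

#' Three-stage clonal expansion hazard (structural form)
#'
#' \deqn{h_3(t) = \nu X \left[1 - \left(\frac{q-p}{q e^{-pt} - p e^{-qt}}
#' \right)^{\mu_1/\alpha}\right].}
#' Bounded above by \eqn{\nu X}, its asymptote as \eqn{t \to \infty} — a
#' feature reached far beyond observable ages for realistic mutation rates,
#' which is the root of the model's practical identifiability problem.
#'
#' The small power \eqn{\mu_1/\alpha} (often ~1e-6) is applied as
#' `expm1(k * log B)` so that \eqn{1 - B^k} retains full precision.
#'
#' @param t age in years (vectorized, >= 0).
#' @param nuX initiation inflow \eqn{\nu X} per year (> 0).
#' @param mu1_over_alpha dimensionless ratio \eqn{\mu_1/\alpha} (> 0).
#' @param pq a [compute_pq()] pair.
#' @return hazard per person-year.
#' @export
hazard_3 <- function(t, nuX, mu1_over_alpha, pq) {
  .check_hazard_args(t, pq)
  if (!is.finite(nuX) || nuX <= 0) stop("nuX must be > 0")
  if (!is.finite(mu1_over_alpha) || mu1_over_alpha <= 0)
    stop("mu1_over_alpha must be > 0")
  h <- -nuX * expm1(mu1_over_alpha * .log_base_ratio(t, pq$p, pq$q))
  if (any(is.nan(h))) stop("hazard_3 produced NaN")
  h
}

#' Three-stage hazard in the practically identifiable parameterization
#'
#' Substitutes \eqn{\nu X = r_3\sqrt{\alpha X}} and
#' \eqn{\mu_1/\alpha = r_3/\sqrt{\alpha X}} into the three-stage hazard,
#' where \eqn{r_3 = \sqrt{(\nu X)(\mu_1/\alpha)}} is the identifiable
#' composite preinitiation rate. `fixed_X` and `fixed_alpha` only need to be
#' "reasonable" (inside the flat region of the likelihood); the fit is
#' invariant to their exact values.
#'
#' @param t age in years.
#' @param r3 composite preinitiation rate (> 0).
#' @param fixed_X normal-cell count used in the substitution (> 0).
#' @param fixed_alpha division rate used in the substitution (> 0).
#' @param pq a [compute_pq()] pair.
#' @return hazard per person-year.
#' @export
hazard_3_reparam <- function(t, r3, fixed_X, fixed_alpha, pq) {
  if (any(!is.finite(c(r3, fixed_X, fixed_alpha))) ||
      r3 <= 0 || fixed_X <= 0 || fixed_alpha <= 0)
    stop("r3, fixed_X, fixed_alpha must be > 0")
  sax <- sqrt(fixed_alpha * fixed_X)
  hazard_3(t, nuX = r3 * sax, mu1_over_alpha = r3 / sax, pq = pq)
}

# Cumulative inner integral of the four-stage hazard. The integrand depends
# on the lag s = t - u only, so I(t) = int_0^t g(s) ds is accumulated across
# the sorted evaluation ages with adaptive quadrature per segment; fixed
# 64-point Gauss-Legendre is the fallback if a segment fails to converge.
.h4_inner <- function(t, mu1, k2, p, q, tol) {
  g <- function(s) mu1 * expm1(k2 * .log_base_ratio(s, p, q))
  ord <- order(t)
  ts <- t[ord]
  I <- numeric(length(ts))
  lo <- 0; acc <- 0
  for (i in seq_along(ts)) {
    hi <- ts[i]
    if (hi > lo) {
      val <- tryCatch(
        stats::integrate(g, lo, hi, rel.tol = tol, abs.tol = tol,
                         stop.on.error = TRUE)$value,
        error = function(e) {
          gl <- pracma::gaussLegendre(64, lo, hi)
          sum(gl$w * g(gl$x))
        }
      )
      acc <- acc + val
      lo <- hi
    }
    I[i] <- acc
  }
  out <- numeric(length(t))
  out[ord] <- I
  out
}

#' Four-stage clonal expansion hazard (structural form)
#'
#' \deqn{h_4(t) = \nu X\left[1 - \exp\int_0^t \mu_1\left\{\left(
#' \frac{q-p}{q e^{-p(t-u)} - p e^{-q(t-u)}}\right)^{\mu_2/\alpha} - 1
#' \right\}\mathrm{d}u\right].}
#' The integrand vanishes at \eqn{u = t}, is bounded on \eqn{[0, t]}, and is
#' evaluated by adaptive quadrature to `quadrature_tol`.
#'
#' @param t age in years (vectorized, >= 0).
#' @param nuX initiation inflow \eqn{\nu X} per year (> 0).
#' @param mu1 second preinitiation rate per year (> 0).
#' @param mu2_over_alpha dimensionless ratio \eqn{\mu_2/\alpha} (> 0).
#' @param pq a [compute_pq()] pair.
#' @param quadrature_tol absolute and relative quadrature tolerance.
#' @return hazard per person-year.
#' @export
hazard_4 <- function(t, nuX, mu1, mu2_over_alpha, pq, quadrature_tol = 1e-10) {
  .check_hazard_args(t, pq)
  if (any(!is.finite(c(nuX, mu1, mu2_over_alpha))) ||
      nuX <= 0 || mu1 <= 0 || mu2_over_alpha <= 0)
    stop("nuX, mu1, mu2_over_alpha must be > 0")
  I <- .h4_inner(t, mu1, mu2_over_alpha, pq$p, pq$q, quadrature_tol)
  h <- -nuX * expm1(I)
  if (any(is.nan(h))) stop("hazard_4 produced NaN")
  h
}

#' Four-stage hazard in the practically identifiable parameterization
#'
#' Substitutes \eqn{\nu X = r_4 (X^2\alpha)^{1/3}},
#' \eqn{\mu_1 = r_4 (\alpha/X)^{1/3}}, and
#' \eqn{\mu_2/\alpha = r_4/(\alpha^2 X)^{1/3}} into the four-stage hazard,
#' where \eqn{r_4 = (\nu X \mu_1 \mu_2 / \alpha)^{1/3}}. The product of the
#' three substituted quantities is exactly \eqn{r_4^3}.
#'
#' @inheritParams hazard_3_reparam
#' @param r4 composite preinitiation rate (> 0).
#' @param quadrature_tol absolute and relative quadrature tolerance.
#' @return hazard per person-year.
#' @export
hazard_4_reparam <- function(t, r4, fixed_X, fixed_alpha, pq,
                             quadrature_tol = 1e-10) {
  if (any(!is.finite(c(r4, fixed_X, fixed_alpha))) ||
      r4 <= 0 || fixed_X <= 0 || fixed_alpha <= 0)
    stop("r4, fixed_X, fixed_alpha must be > 0")
  hazard_4(t,
           nuX = r4 * (fixed_X^2 * fixed_alpha)^(1 / 3),
           mu1 = r4 * (fixed_alpha / fixed_X)^(1 / 3),
           mu2_over_alpha = r4 / (fixed_alpha^2 * fixed_X)^(1 / 3),
           pq = pq, quadrature_tol = quadrature_tol)
}
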