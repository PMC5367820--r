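#' Biological parameter set for an n-stage clonal expansion model
#'
#' Bundles the full mechanistic rate set of a multistage clonal expansion
#' (MSCE) model: normal cells acquire an initial mutation at rate `nu` per
#' cell per year, pass through `n_stages - 2` further preinitiation steps at
#' rates `mu[1], ..., mu[n-2]`, and initiated cells undergo clonal expansion
#' (birth rate `alpha`, death rate `beta`) until malignant conversion at rate
#' `mu[n-1]`.
#'
#' @param n_stages integer, number of stages; one of 2, 3, 4.
#' @param nu initial mutation rate per cell per year (>= 0).
#' @param X number of normal (stem) cells at risk; held constant (> 0).
#' @param mu numeric vector of length `n_stages - 1`: the preinitiation /
#'   initiation rates followed by the malignant transformation rate, per year.
#' @param alpha clonal expansion (cell division) rate per year.
#' @param beta cell death rate per year; biologically meaningful hazards
#'   require `alpha > beta`.
#'
#' @return an object of class `"bio_params"`.
#' @examples
#' bio_params(2, nu = 0.01, X = 10, mu = 0.01, alpha = 1, beta = 0.5)
#' @export
bio_params <- function(n_stages, nu, X, mu, alpha, beta) {
  n_stages <- as.integer(n_stages)
  if (!n_stages %in% 2:4)
    stop("n_stages must be 2, 3, or 4")
  rates <- c(nu = nu, alpha = alpha, beta = beta, mu)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (!is.finite(X) || X <= 0)
    stop("X must be a positive cell count")
  if (length(mu) != n_stages - 1L)
    stop("mu must have exactly n_stages - 1 entries")
  structure(
    list(n_stages = n_stages, nu = nu, X = X, mu = as.numeric(mu),
         alpha = alpha, beta = beta),
    class = "bio_params"
  )
}

#' Roots p, q of the initiated-cell quadratic
#'
#' The observable shape of every MSCE hazard is carried by the two real roots
#' of \eqn{z^2 + (\alpha-\beta-\mu)z - \alpha\mu = 0}, where \eqn{\mu} is the
#' malignant transformation rate of initiated cells:
#' \deqn{p, q = \frac{1}{2}\left(-(\alpha-\beta-\mu) \mp
#'   \sqrt{(\alpha-\beta-\mu)^2 + 4\alpha\mu}\right).}
#' The discriminant is always non-negative, `p <= 0 <= q`, and by Vieta
#' `p + q = -(alpha - beta - mu)`, `p * q = -alpha * mu`.
#'
#' Computed with the cancellation-safe branch: the root that would suffer
#' subtractive cancellation is obtained from the product identity
#' \eqn{pq = -\alpha\mu}.
#'
#' @param alpha cell division rate per year (> 0).
#' @param beta cell death rate per year (>= 0).
#' @param mu_last malignant transformation rate per year (>= 0).
#'
#' @return a list of class `"pq_pair"` with elements `p` (<= 0) and `q` (>= 0).
#' @examples
#' compute_pq(alpha = 1, beta = 0.5, mu_last = 0)    # p = -0.5, q = 0
#' compute_pq(alpha = 9, beta = 8.7, mu_last = 1e-5)
#' @export
compute_pq <- function(alpha, beta, mu_last) {
  if (any(!is.finite(c(alpha, beta, mu_last))))
    stop("alpha, beta, mu_last must be finite")
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta < 0 || mu_last < 0) stop("beta and mu_last must be >= 0")
  s <- alpha - beta - mu_last          # net proliferation of initiated cells
  disc <- sqrt(s^2 + 4 * alpha * mu_last)
  if (s >= 0) {
    p <- (-s - disc) / 2
    q <- if (disc + s > 0) (2 * alpha * mu_last) / (disc + s) else 0
  } else {
    q <- (-s + disc) / 2
    p <- if (disc - s > 0) -(2 * alpha * mu_last) / (disc - s) else 0
  }
  structure(list(p = p, q = q), class = "pq_pair")
}

#' Invert a (p, q) pair to the identifiable rate combinations
#'
#' Returns the net cell proliferation rate of initiated cells
#' \eqn{\alpha-\beta-\mu = -(p+q)} and the scaled malignant conversion rate
#' \eqn{\alpha\mu = -pq}; together these are equivalent to (p, q).
#'
#' @param pq a `"pq_pair"` (or list with elements `p`, `q`, `p <= 0 <= q`).
#' @return named numeric vector `c(net_proliferation, alpha_mu)`.
#' @examples
#' invert_pq(compute_pq(1, 0.5, 0))
#' @export
invert_pq <- function(pq) {
  p <- pq$p; q <- pq$q
  if (!is.finite(p) || !is.finite(q) || p > 0 || q < 0)
    stop("pq must satisfy p <= 0 <= q")
  c(net_proliferation = -(p + q), alpha_mu = -(p * q))
}

#' Map a full biological parameter set to its identifiable combinations
#'
#' Computes the practically identifiable triple (p, q, r) together with the
#' structurally identifiable set for the given model:
#' \itemize{
#'   \item 2-stage: \eqn{r_2 = \nu X/\alpha}; structural set is (r2, p, q).
#'   \item 3-stage: \eqn{r_3 = \sqrt{(\nu X)(\mu_1/\alpha)}}; structural set
#'     (\eqn{\nu X}, \eqn{\mu_1/\alpha}, p, q).
#'   \item 4-stage: \eqn{r_4 = (\nu X \mu_1 \mu_2/\alpha)^{1/3}}; structural
#'     set (\eqn{\nu X}, \eqn{\mu_1}, \eqn{\mu_2/\alpha}, p, q).
#' }
#'
#' @param bio a [bio_params()] object.
#' @return list of class `"identifiable_params"` with elements `n_stages`,
#'   `p`, `q`, `r`, and `structural` (named list of the structural
#'   combinations beyond p, q).
#' @export
bio_to_identifiable <- function(bio) {
  stopifnot(inherits(bio, "bio_params"))
  n <- bio$n_stages
  pq <- compute_pq(bio$alpha, bio$beta, bio$mu[n - 1L])
  nuX <- bio$nu * bio$X
  structural <- switch(
    as.character(n),
    "2" = list(r2 = nuX / bio$alpha),
    "3" = list(nuX = nuX, mu1_over_alpha = bio$mu[1] / bio$alpha),
    "4" = list(nuX = nuX, mu1 = bio$mu[1], mu2_over_alpha = bio$mu[2] / bio$alpha)
  )
  r <- switch(
    as.character(n),
    "2" = nuX / bio$alpha,
    "3" = sqrt(nuX * bio$mu[1] / bio$alpha),
    "4" = (nuX * bio$mu[1] * bio$mu[2] / bio$alpha)^(1 / 3)
  )
  structure(
    list(n_stages = n, p = pq$p, q = pq$q, r = r, structural = structural),
    class = "identifiable_params"
  )
}
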