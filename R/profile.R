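# Profile likelihoods and likelihood-based confidence intervals: the
# operational machinery of practical identifiability. A parameter is
# profiled by fixing it on a log-spaced grid and re-optimizing the
# remaining parameters at every grid point (warm-started from the
# neighbouring point, with a restart from the global optimum as guard).

.refit_fixed <- function(model, table, theta_full, fix_idx, warm_free) {
  obj <- .nll_obj(model, table, free_idx = setdiff(seq_along(theta_full),
                                                   fix_idx),
                  theta_full = theta_full)
  res <- tryCatch(.optimize_from(obj, warm_free, polish = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) list(par = warm_free, objective = Inf, convergence = 1L)
  else res
}

#' Profile likelihood of one parameter
#'
#' Fixes `param` at a series of log-spaced values and minimizes the negative
#' log-likelihood over the remaining parameters at each. The grid starts at
#' +/- `init_decades` around the MLE with `n_per_decade` points per decade
#' and auto-extends outward, one decade at a time, until the relative NLL
#' crosses `threshold` on that side or `max_decades` decades from the MLE
#' are spanned — so a flat (practically unidentifiable) direction is probed
#' over many orders of magnitude before giving up.
#'
#' @param model an [msce_model()].
#' @param table an [incidence_table()].
#' @param fit the converged global [fit_mle()] result.
#' @param param name of the parameter to profile (one of
#'   `model$par_names`).
#' @param n_per_decade grid density (default 10).
#' @param init_decades initial half-width in decades (default 1).
#' @param max_decades maximum decades searched per side (default 6).
#' @param threshold relative-NLL level that stops the extension; defaults to
#'   the simultaneous 99\% threshold \eqn{\chi^2(0.01, k)/2} (times a small
#'   headroom factor so the crossing itself is bracketed).
#' @return a `"profile_curve"`: data frame with columns `value` (natural
#'   scale), `nll`, `rel_nll`, `converged`, and the co-parameter values
#'   (`co_*`); attributes `param`, `ref_nll`, `n_params`,
#'   `searched_decades`.
#' @export
profile_likelihood <- function(model, table, fit, param,
                               n_per_decade = 10, init_decades = 1,
                               max_decades = 6, threshold = NULL) {
  stopifnot(inherits(fit, "msce_fit"))
  idx <- match(param, model$par_names)
  if (is.na(idx)) stop("unknown parameter: ", param)
  if (length(model$par_names) < 2) stop("nothing to profile over")
  if (is.null(threshold))
    threshold <- stats::qchisq(0.99, length(model$par_names)) / 2
  stop_level <- threshold * 1.2 + 0.5   # bracket the crossing comfortably

  theta_hat <- .to_log(model, fit$params)
  step <- log(10) / n_per_decade
  free_idx <- setdiff(seq_along(theta_hat), idx)

  march <- function(direction) {
    out <- list(); warm <- theta_hat[free_idx]
    offs <- step * seq_len(init_decades * n_per_decade)
    i <- 1
    while (i <= length(offs)) {
      th <- theta_hat
      th[idx] <- theta_hat[idx] + direction * offs[i]
      res <- .refit_fixed(model, table, th, idx, warm)
      res2 <- .refit_fixed(model, table, th, idx, theta_hat[free_idx])
      if (res2$objective < res$objective) res <- res2
      warm <- res$par
      th[free_idx] <- res$par
      out[[i]] <- c(offset = direction * offs[i], nll = res$objective,
                    converged = as.numeric(res$convergence == 0 ||
                                             is.finite(res$objective)),
                    th)
      # extend while this side has not crossed the stop level
      if (i == length(offs) &&
          offs[i] < max_decades * log(10) - 1e-9 &&
          (res$objective - fit$nll) < stop_level) {
        offs <- c(offs, offs[i] + step * seq_len(n_per_decade))
      }
      i <- i + 1
    }
    out
  }

  rows <- c(rev(march(-1)),
            list(c(offset = 0, nll = fit$nll, converged = 1, theta_hat)),
            march(+1))
  m <- do.call(rbind, rows)
  theta_cols <- m[, model$par_names, drop = FALSE]
  nat <- t(apply(theta_cols, 1, function(th) .from_log(model, th)))
  colnames(nat) <- model$par_names
  ref <- min(fit$nll, m[, "nll"])
  df <- data.frame(value = nat[, param],
                   nll = m[, "nll"],
                   rel_nll = m[, "nll"] - ref,
                   converged = m[, "converged"] > 0)
  co <- nat[, setdiff(model$par_names, param), drop = FALSE]
  colnames(co) <- paste0("co_", colnames(co))
  df <- cbind(df, co)
  df <- df[order(df$value), ]
  rownames(df) <- NULL
  structure(df,
            param = param, ref_nll = ref,
            n_params = length(model$par_names),
            mle_value = fit$params[[param]],
            searched_decades = max(abs(m[, "offset"])) / log(10),
            class = c("profile_curve", "data.frame"))
}

#' Likelihood-based confidence interval from a profile curve
#'
#' The CI at significance `alpha` is the set of profiled values whose
#' relative negative log-likelihood lies below
#' \eqn{\Delta_\alpha = \chi^2(\alpha, \mathrm{df})/2}, with df equal to the
#' number of fitted parameters for simultaneous intervals (the default
#' convention) or 1 for pointwise intervals. Bounds are located by monotone
#' interpolation of the threshold crossing on the log scale of the
#' parameter; a side that never crosses within the searched grid is flagged
#' unbounded-within-searched-range rather than reported as infinite.
#'
#' @param curve a [profile_likelihood()] result (>= 5 points).
#' @param alpha significance level (default 0.01, as in simultaneous 99\%
#'   intervals).
#' @param df degrees of freedom for the chi-squared threshold; default = the
#'   number of fitted parameters recorded in the curve (simultaneous).
#' @return a `"likelihood_ci"` list: `alpha`, `df`, `threshold`, `lower`,
#'   `upper`, `lower_unbounded`, `upper_unbounded`, `mle`,
#'   `searched_range`.
#' @export
likelihood_ci <- function(curve, alpha = 0.01, df = NULL) {
  stopifnot(inherits(curve, "profile_curve"), nrow(curve) >= 5)
  if (is.null(df)) df <- attr(curve, "n_params")
  delta <- stats::qchisq(1 - alpha, df) / 2
  rel <- curve$rel_nll
  if (all(rel > delta))
    stop("entire profile lies above the threshold; the global fit failed")
  i_min <- which.min(rel)
  x <- log(abs(curve$value))          # all profiled values share one sign
  sgn <- sign(curve$value[i_min])

  cross <- function(idx_seq, other_side) {
    # walk from the minimum outward; first bracket of the threshold.
    # Local quadratic interpolation (through the bracket and its inner
    # neighbour) keeps the bound stable under grid refinement; falls back
    # to linear when the quadratic has no root inside the bracket.
    for (j in seq_along(idx_seq)[-1]) {
      a <- idx_seq[j - 1]; b <- idx_seq[j]
      if (rel[a] < delta && rel[b] >= delta) {
        lin <- x[a] + (delta - rel[a]) / (rel[b] - rel[a]) * (x[b] - x[a])
        xc <- lin
        c3 <- if (j > 2) idx_seq[j - 2] else other_side
        if (!is.na(c3)) {
          xs <- x[c(c3, a, b)]; ys <- rel[c(c3, a, b)]
          co <- tryCatch(solve(cbind(1, xs, xs^2), ys),
                         error = function(e) NULL)
          if (!is.null(co) && abs(co[3]) > 1e-12) {
            disc <- co[2]^2 - 4 * co[3] * (co[1] - delta)
            if (disc >= 0) {
              roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
              inb <- roots[roots >= min(x[a], x[b]) &
                             roots <= max(x[a], x[b])]
              if (length(inb)) xc <- inb[which.min(abs(inb - lin))]
            }
          }
        }
        return(sgn * exp(xc))
      }
    }
    NA_real_
  }
  lower <- cross(seq(i_min, 1),
                 if (i_min < nrow(curve)) i_min + 1L else NA_integer_)
  upper <- cross(seq(i_min, nrow(curve)),
                 if (i_min > 1) i_min - 1L else NA_integer_)
  structure(
    list(alpha = alpha, df = df, threshold = delta,
         lower = lower, upper = upper,
         lower_unbounded = is.na(lower), upper_unbounded = is.na(upper),
         mle = attr(curve, "mle_value"),
         searched_range = range(curve$value)),
    class = "likelihood_ci")
}

#' Classify a parameter as practically identifiable or not
#'
#' A parameter is identifiable when both likelihood-CI bounds are finite
#' within the searched range. If a bound was not crossed, the verdict is
#' `"practically_unidentifiable"` provided the profile grid spanned at least
#' `min_decades` orders of magnitude — otherwise the search was too narrow
#' to tell and the verdict is `"indeterminate"`. The searched range is
#' always reported with the verdict.
#'
#' @param curve a [profile_likelihood()] result.
#' @param ci the matching [likelihood_ci()].
#' @param min_decades minimum grid span (orders of magnitude) required to
#'   declare practical unidentifiability (default 4).
#' @return list with `verdict` (one of `"identifiable"`,
#'   `"practically_unidentifiable"`, `"indeterminate"`),
#'   `searched_decades`, `searched_range`.
#' @export
classify_practical_identifiability <- function(curve, ci, min_decades = 4) {
  stopifnot(inherits(curve, "profile_curve"), inherits(ci, "likelihood_ci"))
  span <- log10(max(abs(curve$value)) / min(abs(curve$value)))
  verdict <- if (!ci$lower_unbounded && !ci$upper_unbounded) {
    "identifiable"
  } else if (span >= min_decades) {
    "practically_unidentifiable"
  } else {
    "indeterminate"
  }
  list(verdict = verdict, searched_decades = span,
       searched_range = ci$searched_range)
}

#' Subset-profiling dependency scan
#'
#' Varies one structural parameter over a log-spaced grid inside the flat
#' region of the likelihood, refits the remaining free parameters at every
#' grid value (optionally with a second parameter held fixed, as needed for
#' the 4-stage model), and regresses the fitted value of a responding
#' parameter on the varied one on the log-log scale. A slope of -1 with an
#' essentially perfect linear fit certifies that the two (or, jointly over
#' three scans, three) parameters are practically identifiable only through
#' their product.
#'
#' @param model a structural-form [msce_model()].
#' @param table an [incidence_table()].
#' @param fit converged global [fit_mle()] result.
#' @param varied name of the parameter stepped along `grid`.
#' @param grid positive grid of values for `varied` (log-spaced, spanning
#'   several decades of the flat region).
#' @param responding name of the parameter whose refitted value is tracked.
#' @param fixed optional `list(name = , value = )` holding a third parameter
#'   constant throughout the scan.
#' @param max_fail maximum fraction of non-converged grid refits tolerated
#'   before the scan is invalidated (default 0.2).
#' @return a `"dependency_scan"`: data frame (`varied`, `responding`,
#'   `nll`, `converged`, `product`) with attributes `slope`, `intercept`,
#'   `r_squared` from the log-log OLS fit, and the scan configuration.
#' @export
dependency_scan <- function(model, table, fit, varied, grid, responding,
                            fixed = NULL, max_fail = 0.2) {
  stopifnot(inherits(fit, "msce_fit"))
  vi <- match(varied, model$par_names)
  ri <- match(responding, model$par_names)
  if (is.na(vi) || is.na(ri)) stop("unknown parameter name")
  if (any(grid <= 0)) stop("grid must be positive (rate-like parameters)")
  grid <- sort(grid)
  fix_idx <- vi
  theta_hat <- .to_log(model, fit$params)
  if (!is.null(fixed)) {
    fi <- match(fixed$name, model$par_names)
    if (is.na(fi)) stop("unknown fixed parameter")
    theta_hat[fi] <- log(fixed$value)
    fix_idx <- c(vi, fi)
  }
  free_idx <- setdiff(seq_along(theta_hat), fix_idx)

  # march from the grid point nearest the MLE outward in both directions
  start_j <- which.min(abs(log(grid) - theta_hat[vi]))
  order_js <- c(rev(seq_len(start_j)), seq(start_j + 1, length.out =
                                             length(grid) - start_j))
  # count-matched start for the responding (level-like) parameter: with the
  # varied/fixed coordinates pinned, solve the responding coordinate so that
  # total expected cases match total observed cases — rescues refits whose
  # warm start sits on the infeasible plateau far along the flat direction
  count_start <- function(th) {
    g <- function(lx) {
      th[ri] <- lx
      sum(expected_cases(model, .from_log(model, th), table)) -
        max(sum(table$cases), 1)
    }
    lx <- tryCatch(stats::uniroot(g, c(-60, 60), tol = 1e-6)$root,
                   error = function(e) NA_real_)
    if (is.na(lx)) return(NULL)
    th[ri] <- lx
    th[free_idx]
  }

  rows <- vector("list", length(grid))
  warm_l <- warm_r <- theta_hat[free_idx]
  for (j in order_js) {
    th <- theta_hat
    th[vi] <- log(grid[j])
    warm <- if (j <= start_j) warm_l else warm_r
    res <- .refit_fixed(model, table, th, fix_idx, warm)
    res2 <- .refit_fixed(model, table, th, fix_idx, theta_hat[free_idx])
    if (res2$objective < res$objective) res <- res2
    cs <- count_start(th)
    if (!is.null(cs)) {
      res3 <- .refit_fixed(model, table, th, fix_idx, cs)
      if (res3$objective < res$objective) res <- res3
    }
    if (j <= start_j) warm_l <- res$par else warm_r <- res$par
    th[free_idx] <- res$par
    nat <- .from_log(model, th)
    rows[[j]] <- data.frame(
      varied = grid[j], responding = nat[[responding]],
      nll = res$objective,
      converged = is.finite(res$objective) &&
        (res$convergence == 0 || res$objective < fit$nll + 1e3))
  }
  df <- do.call(rbind, rows)
  df$product <- df$varied * df$responding
  if (mean(!df$converged) > max_fail)
    stop("more than ", 100 * max_fail, "% of scan refits failed to converge")
  ok <- df$converged
  ols <- stats::lm(log10(responding) ~ log10(varied), data = df[ok, ])
  structure(df,
            slope = unname(stats::coef(ols)[2]),
            intercept = unname(stats::coef(ols)[1]),
            r_squared = summary(ols)$r.squared,
            varied_name = varied, responding_name = responding,
            fixed = fixed,
            class = c("dependency_scan", "data.frame"))
}
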