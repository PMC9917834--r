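new_mr_result <- function(method, beta, se, p, k, extra = list()) {
  z <- qnorm(0.975)
  structure(list(method = method, beta = beta, se = se, p = p,
                 or_value = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 k = k, extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (k = %d): beta = %.4g (SE %.4g), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$k, x$beta, x$se, x$or_value, x$ci_low, x$ci_high, x$p))
  if (!is.null(x$extra$intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                x$extra$intercept, x$extra$intercept_se, x$extra$intercept_p))
  }
  invisible(x)
}

# per-instrument Wald ratios and their first-order standard errors
wald_ratios <- function(ivs) {
  list(ratio = ivs$beta_outcome / ivs$beta_exposure,
       se = ivs$se_outcome / abs(ivs$beta_exposure))
}

#' Wald ratio causal estimate for a single instrument
#'
#' Ratio of the outcome effect to the exposure effect, with the first-order
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param row A one-row `harmonized_ivs` (or equivalent data.frame row).
#' @return An `mr_result`.
#' @export
wald_ratio <- function(row) {
  stopifnot(nrow(row) == 1)
  if (row$beta_exposure == 0) stop("wald_ratio: undefined for beta_exposure = 0")
  est <- row$beta_outcome / row$beta_exposure
  se <- row$se_outcome / abs(row$beta_exposure)
  new_mr_result("wald", est, se, 2 * pnorm(-abs(est) / se), 1L)
}

#' Random-effects inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome on exposure effects through the origin with
#' weights `1/se_outcome^2`; the multiplicative random-effects model scales the
#' fixed-effect SE by `max(1, sqrt(Q / (k - 1)))`, so the random-effects SE is
#' never smaller than the fixed-effect one. With a single instrument the
#' estimate falls back to the Wald ratio with a warning.
#'
#' @param ivs A `harmonized_ivs` table with k >= 1 rows.
#' @return An `mr_result` (method `ivw_re`); `extra` carries `q`, `q_df` and
#'   the fixed-effect SE.
#' @export
ivw_random_effects <- function(ivs) {
  k <- nrow(ivs)
  if (k < 1) stop("ivw_random_effects: no instruments")
  if (k < 2) {
    warning("ivw_random_effects: k = 1, falling back to the Wald ratio")
    res <- wald_ratio(ivs)
    res$method <- "ivw_re"
    return(res)
  }
  w <- 1 / ivs$se_outcome^2
  bx <- ivs$beta_exposure; by <- ivs$beta_outcome
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  scale <- max(1, sqrt(q / (k - 1)))
  se <- se_fixed * scale
  new_mr_result("ivw_re", beta, se, 2 * pnorm(-abs(beta) / se), k,
                extra = list(q = q, q_df = k - 1, se_fixed = se_fixed, scale = scale))
}

#' MR-Egger regression
#'
#' Rows are oriented so all exposure effects are non-negative, then outcome
#' effects are regressed on exposure effects with a free intercept, weights
#' `1/se_outcome^2`. The slope is the causal estimate; the intercept estimates
#' average directional pleiotropy. SEs carry the multiplicative dispersion
#' factor `max(1, sqrt(Q' / (k - 2)))`; p-values use a t distribution on k - 2
#' degrees of freedom.
#'
#' @param ivs A `harmonized_ivs` table with k >= 3 rows.
#' @return An `mr_result` (method `egger`) with intercept fields in `extra`,
#'   or a method-unavailable result when k < 3.
#' @export
mr_egger <- function(ivs) {
  k <- nrow(ivs)
  if (k < 3) return(mr_unavailable("egger", k, "needs at least 3 instruments"))
  flip <- sign(ivs$beta_exposure)
  flip[flip == 0] <- 1
  bx <- ivs$beta_exposure * flip
  by <- ivs$beta_outcome * flip
  w <- 1 / ivs$se_outcome^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  den <- sw * swxx - swx^2
  if (abs(den) < .Machine$double.eps * sw * swxx) {
    return(mr_unavailable("egger", k, "degenerate exposure effects"))
  }
  slope <- (sw * swxy - swx * swy) / den
  inter <- (swy - slope * swx) / sw
  qr_ <- sum(w * (by - inter - slope * bx)^2)
  scale <- max(1, sqrt(qr_ / (k - 2)))
  se_slope <- sqrt(sw / den) * scale
  se_inter <- sqrt(swxx / den) * scale
  p_slope <- 2 * pt(-abs(slope) / se_slope, df = k - 2)
  p_inter <- 2 * pt(-abs(inter) / se_inter, df = k - 2)
  new_mr_result("egger", slope, se_slope, p_slope, k,
                extra = list(intercept = inter, intercept_se = se_inter,
                             intercept_p = p_inter, q_rucker = qr_, q_df = k - 2,
                             scale = scale))
}

mr_unavailable <- function(method, k, why) {
  structure(list(method = method, beta = NA_real_, se = NA_real_, p = NA_real_,
                 or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 k = k, extra = list(unavailable = why)),
            class = "mr_result")
}

# interpolated weighted median of ratios r with weights w; if a single
# instrument carries a majority of the weight its ratio is returned outright.
weighted_median_point <- function(r, w) {
  w <- w / sum(w)
  if (any(w > 0.5)) return(r[which.max(w)])
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  below <- max(which(s < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

# parametric bootstrap SE: resample effects from their sampling distributions
# and recompute the point estimator
bootstrap_se <- function(ivs, point_fun, n_boot, seed) {
  k <- nrow(ivs)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(k, ivs$beta_exposure, ivs$se_exposure)
      by <- rnorm(k, ivs$beta_outcome, ivs$se_outcome)
      point_fun(bx, by)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' The interpolated 50th weighted percentile of the per-instrument Wald
#' ratios, with inverse-variance weights; consistent when instruments holding
#' at least half the weight are valid. SE by seeded parametric bootstrap.
#'
#' @param ivs A `harmonized_ivs` table with k >= 3 rows.
#' @param n_boot Bootstrap draws for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result` (method `weighted_median`).
#' @export
weighted_median <- function(ivs, n_boot = 1000, seed = 1) {
  k <- nrow(ivs)
  if (k < 3) return(mr_unavailable("weighted_median", k, "needs at least 3 instruments"))
  wr <- wald_ratios(ivs)
  est <- weighted_median_point(wr$ratio, 1 / wr$se^2)
  se <- bootstrap_se(ivs, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / ivs$se_outcome^2)
  }, n_boot, seed)
  new_mr_result("weighted_median", est, se, 2 * pnorm(-abs(est) / se), k)
}

# kernel-smoothed mode of ratios: argmax over a fine grid of the weighted
# normal-kernel sum; bandwidth = phi * 0.9 * min(sd, mad/0.6745-free mad) * k^-0.2
mode_point <- function(r, w, phi = 1, n_grid = 4096) {
  k <- length(r)
  s <- 0.9 * min(sd(r), mad(r)) * k^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- 0.9 * max(sd(r), 1e-8) * k^(-1 / 5)
  h <- phi * s
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = n_grid)
  dens <- colSums(w * dnorm(outer(r, grid, "-") / h))
  grid[which.max(dens)]
}

mode_estimator <- function(ivs, weighted, phi, n_boot, seed) {
  k <- nrow(ivs)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  if (k < 3) return(mr_unavailable(method, k, "needs at least 3 instruments"))
  wr <- wald_ratios(ivs)
  w <- if (weighted) (1 / wr$se^2) else rep(1, k)
  est <- mode_point(wr$ratio, w / sum(w), phi)
  se <- bootstrap_se(ivs, function(bx, by) {
    r <- by / bx
    wb <- if (weighted) bx^2 / ivs$se_outcome^2 else rep(1, k)
    mode_point(r, wb / sum(wb), phi)
  }, n_boot, seed)
  new_mr_result(method, est, se, 2 * pnorm(-abs(est) / se), k,
                extra = list(phi = phi))
}

#' Simple-mode causal estimate
#'
#' Mode of the kernel-smoothed density of the per-instrument Wald ratios
#' (unweighted); consistent under the ZEMPA assumption that the largest group
#' of instruments with equal ratios is valid. SE by seeded parametric
#' bootstrap.
#'
#' @param ivs A `harmonized_ivs` table with k >= 3 rows.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot,seed Bootstrap settings.
#' @return An `mr_result` (method `simple_mode`).
#' @export
simple_mode <- function(ivs, phi = 1, n_boot = 1000, seed = 1) {
  mode_estimator(ivs, weighted = FALSE, phi, n_boot, seed)
}

#' Weighted-mode causal estimate
#'
#' As [simple_mode()] but each ratio contributes with inverse-variance weight.
#'
#' @inheritParams simple_mode
#' @return An `mr_result` (method `weighted_mode`).
#' @export
weighted_mode <- function(ivs, phi = 1, n_boot = 1000, seed = 1) {
  mode_estimator(ivs, weighted = TRUE, phi, n_boot, seed)
}

#' Run the full five-estimator battery
#'
#' Random-effects IVW (the main method) plus MR-Egger, weighted median, simple
#' mode and weighted mode as supplementary methods.
#'
#' @param ivs A `harmonized_ivs` table.
#' @param phi Mode bandwidth multiplier.
#' @param n_boot,seed Bootstrap settings for median/mode SEs.
#' @return A named list of `mr_result` objects.
#' @export
mr_all <- function(ivs, phi = 1, n_boot = 1000, seed = 1) {
  list(ivw_re = ivw_random_effects(ivs),
       egger = mr_egger(ivs),
       weighted_median = weighted_median(ivs, n_boot, seed),
       simple_mode = simple_mode(ivs, phi, n_boot, seed + 1L),
       weighted_mode = weighted_mode(ivs, phi, n_boot, seed + 2L))
}

#' Tabulate estimator results (forest-plot-shaped table)
#'
#' @param results A named list of `mr_result` objects (from [mr_all()]).
#' @return data.frame with method, k, beta, se, OR, 95% CI and p.
#' @export
mr_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, k = r$k, beta = r$beta, se = r$se,
               or_value = r$or_value, ci_low = r$ci_low, ci_high = r$ci_high,
               p = r$p, stringsAsFactors = FALSE)
  }))
}
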