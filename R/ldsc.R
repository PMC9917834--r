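#' Per-SNP chi-square association statistics
#'
#' `chi2 = (beta / se)^2` per SNP; the dependent variable of LD score
#' regression.
#'
#' @param table A `sumstats` table (se > 0 for all rows).
#' @return Numeric vector of chi-square statistics, named by SNP id.
#' @export
chi2_stats <- function(table) {
  setNames((table$beta / table$se)^2, table$snp_id)
}

# weighted regression with intercept from the 5 sufficient sums
# (sum w, sum wx, sum wy, sum wxx, sum wxy); works on a matrix of sums too.
.wls_from_sums <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, 1)
  den <- s[, 1] * s[, 4] - s[, 2]^2
  slope <- (s[, 1] * s[, 5] - s[, 2] * s[, 3]) / den
  intercept <- (s[, 3] - slope * s[, 2]) / s[, 1]
  cbind(slope = slope, intercept = intercept)
}

.wls_sums <- function(x, y, w) c(sum(w), sum(w * x), sum(w * y), sum(w * x^2), sum(w * x * y))

# delete-one-block slope/intercept estimates: totals minus per-block sums
.jackknife_fits <- function(x, y, w, blk) {
  mat <- cbind(w, w * x, w * y, w * x^2, w * x * y)
  tot <- colSums(mat)
  bs <- rowsum(mat, blk)
  del <- sweep(-bs, 2, tot, "+")
  list(full = .wls_from_sums(tot), del = .wls_from_sums(del), n_blocks = nrow(bs))
}

.jackknife_se <- function(theta_d) {
  nb <- length(theta_d)
  sqrt((nb - 1) / nb * sum((theta_d - mean(theta_d))^2))
}

# LDSC regression weights: 1/ell over-counting correction times the squared
# expected statistic (heteroskedasticity); intercepts held at 1 inside the
# weights. For the cross-trait regression the variance of z_x * z_y is
# approximated by a_x * a_y + (expected product)^2.
.w_h2 <- function(ell, xreg, h2_cur) {
  1 / (pmax(ell, 1) * (pmax(h2_cur, 0) * xreg + 1)^2)
}
.w_gencov <- function(ell, xx, xy, xg, h2x_cur, h2y_cur, g_cur) {
  ax <- pmax(h2x_cur, 0) * xx + 1
  ay <- pmax(h2y_cur, 0) * xy + 1
  1 / (pmax(ell, 1) * (ax * ay + (g_cur * xg + 1)^2))
}

.ldsc_prepare <- function(table, ld, n_blocks, caller) {
  df <- merge(as.data.frame(table), as.data.frame(ld), by = "snp_id", sort = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  n <- nrow(df)
  if (n < 2 * n_blocks) {
    stop(sprintf("%s: too few overlapping SNPs (%d) for %d jackknife blocks",
                 caller, n, n_blocks))
  }
  if (stats::var(df$ldscore) == 0) {
    stop(sprintf("%s: degenerate (constant) LD scores; regression is singular", caller))
  }
  df$blk <- ceiling(seq_len(n) * n_blocks / n)
  df
}

#' SNP heritability by LD score regression
#'
#' Regresses per-SNP chi-square on `N * l / M` with a free intercept. Weights
#' combine the heteroskedasticity correction `1 / (N h2 l / M + 1)^2` and the
#' over-counting correction `1 / l`, iterated twice from an initial unweighted
#' fit. Standard errors come from a delete-one-block jackknife over contiguous
#' equal-count SNP blocks in genome order.
#'
#' @param table A `sumstats` table with the `n` column filled.
#' @param ld An `ldscores` table (attribute `m_total` supplies M).
#' @param n_blocks Jackknife blocks (default 200); needs at least
#'   `2 * n_blocks` overlapping SNPs.
#' @return An `h2_estimate`: `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_blocks_used`, `n_snps`.
#' @export
fit_h2 <- function(table, ld, n_blocks = 200) {
  df <- .ldsc_prepare(table, ld, n_blocks, "fit_h2")
  m <- attr(ld, "m_total")
  y <- (df$beta / df$se)^2
  xreg <- df$n * df$ldscore / m
  if (any(is.na(xreg))) stop("fit_h2: sample size column 'n' is required for LDSC")

  w <- rep(1, nrow(df))
  fit <- .wls_from_sums(.wls_sums(xreg, y, w))
  for (pass in 1:2) {
    w <- .w_h2(df$ldscore, xreg, fit[1, "slope"])
    fit <- .wls_from_sums(.wls_sums(xreg, y, w))
  }
  jk <- .jackknife_fits(xreg, y, w, df$blk)
  structure(list(h2 = unname(jk$full[1, "slope"]),
                 h2_se = .jackknife_se(jk$del[, "slope"]),
                 intercept = unname(jk$full[1, "intercept"]),
                 intercept_se = .jackknife_se(jk$del[, "intercept"]),
                 n_blocks_used = jk$n_blocks, n_snps = nrow(df)),
            class = "h2_estimate")
}

#' Bivariate genetic correlation by cross-trait LD score regression
#'
#' Regresses `z_x * z_y` on `sqrt(N_x N_y) * l / M` to estimate the genetic
#' covariance, with the two marginal heritability regressions run in lockstep
#' (shared SNPs, shared jackknife blocks, two iterated weight passes from a
#' common unweighted start). `rg = gencov / sqrt(h2_x * h2_y)`; its SE comes
#' from recomputing the ratio on every delete-one-block replicate, and the
#' two-sided p-value from the normal approximation `rg / rg_se`. Estimates
#' outside [-1, 1] are reported with a warning, never clamped.
#'
#' @param x,y `sumstats` tables for the two traits.
#' @param ld An `ldscores` table.
#' @param n_blocks Jackknife blocks (default 200).
#' @param intercept_gencov Optional fixed cross-trait intercept (sample-overlap
#'   constraint); when supplied the covariance regression is forced through it.
#' @return An `rg_estimate`: `rg`, `rg_se`, `p`, `gencov`, `gencov_intercept`,
#'   `h2_x`, `h2_y` (component `h2_estimate`s), `n_blocks_used`.
#' @export
fit_rg <- function(x, y, ld, n_blocks = 200, intercept_gencov = NULL) {
  xy <- merge(as.data.frame(x), as.data.frame(y), by = "snp_id",
              sort = FALSE, suffixes = c("_x", "_y"))
  xy$chrom <- xy$chrom_x; xy$pos <- xy$pos_x
  df <- .ldsc_prepare(xy, ld, n_blocks, "fit_rg")
  m <- attr(ld, "m_total")
  zx <- df$beta_x / df$se_x
  zy <- df$beta_y / df$se_y
  xx <- df$n_x * df$ldscore / m
  xyv <- df$n_y * df$ldscore / m
  xg <- sqrt(df$n_x * df$n_y) * df$ldscore / m
  if (any(is.na(xg))) stop("fit_rg: sample size columns are required for LDSC")

  fit_g_pass <- function(w) {
    if (is.null(intercept_gencov)) {
      .wls_from_sums(.wls_sums(xg, zx * zy, w))
    } else {
      yv <- zx * zy - intercept_gencov
      cbind(slope = sum(w * xg * yv) / sum(w * xg^2), intercept = intercept_gencov)
    }
  }

  w1 <- w2 <- wg <- rep(1, nrow(df))
  fx <- .wls_from_sums(.wls_sums(xx, zx^2, w1))
  fy <- .wls_from_sums(.wls_sums(xyv, zy^2, w2))
  fg <- fit_g_pass(wg)
  for (pass in 1:2) {
    w1 <- .w_h2(df$ldscore, xx, fx[1, "slope"])
    w2 <- .w_h2(df$ldscore, xyv, fy[1, "slope"])
    wg <- .w_gencov(df$ldscore, xx, xyv, xg, fx[1, "slope"], fy[1, "slope"], fg[1, "slope"])
    fx <- .wls_from_sums(.wls_sums(xx, zx^2, w1))
    fy <- .wls_from_sums(.wls_sums(xyv, zy^2, w2))
    fg <- fit_g_pass(wg)
  }

  jx <- .jackknife_fits(xx, zx^2, w1, df$blk)
  jy <- .jackknife_fits(xyv, zy^2, w2, df$blk)
  jg <- if (is.null(intercept_gencov)) {
    .jackknife_fits(xg, zx * zy, wg, df$blk)
  } else {
    yv <- zx * zy - intercept_gencov
    mat <- cbind(wg * xg * yv, wg * xg^2)
    tot <- colSums(mat); bs <- rowsum(mat, df$blk)
    del_s <- (tot[1] - bs[, 1]) / (tot[2] - bs[, 2])
    list(full = cbind(slope = tot[1] / tot[2], intercept = intercept_gencov),
         del = cbind(slope = del_s, intercept = intercept_gencov),
         n_blocks = nrow(bs))
  }

  h2x <- unname(jx$full[1, "slope"]); h2y <- unname(jy$full[1, "slope"])
  gencov <- unname(jg$full[1, "slope"])
  if (h2x <= 0 || h2y <= 0) {
    stop(sprintf("fit_rg: rg undefined — non-positive heritability estimate (h2_x = %.4g, h2_y = %.4g)",
                 h2x, h2y))
  }
  rg <- gencov / sqrt(h2x * h2y)
  if (abs(rg) > 1) warning(sprintf("fit_rg: rg estimate %.3f outside [-1, 1]; reported unclamped", rg))

  prod_d <- jx$del[, "slope"] * jy$del[, "slope"]
  valid <- prod_d > 0
  if (sum(valid) < 2) stop("fit_rg: jackknife replicates degenerate (non-positive h2 products)")
  rg_d <- jg$del[valid, "slope"] / sqrt(prod_d[valid])
  rg_se <- .jackknife_se(rg_d)
  p <- 2 * pnorm(-abs(rg) / rg_se)

  h2_obj <- function(j) {
    structure(list(h2 = unname(j$full[1, "slope"]), h2_se = .jackknife_se(j$del[, "slope"]),
                   intercept = unname(j$full[1, "intercept"]),
                   intercept_se = .jackknife_se(j$del[, "intercept"]),
                   n_blocks_used = j$n_blocks, n_snps = nrow(df)),
              class = "h2_estimate")
  }
  structure(list(rg = rg, rg_se = rg_se, p = p, gencov = gencov,
                 gencov_intercept = unname(jg$full[1, "intercept"]),
                 h2_x = h2_obj(jx), h2_y = h2_obj(jy),
                 n_blocks_used = sum(valid), n_snps = nrow(df)),
            class = "rg_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d SNPs / %d blocks\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$n_snps, x$n_blocks_used))
  invisible(x)
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("LDSC rg = %.4f (SE %.4f), p = %.3g; gencov = %.4g (intercept %.4g)\n",
              x$rg, x$rg_se, x$p, x$gencov, x$gencov_intercept))
  cat(sprintf("  h2_x = %.4f (SE %.4f), h2_y = %.4f (SE %.4f)\n",
              x$h2_x$h2, x$h2_x$h2_se, x$h2_y$h2, x$h2_y$h2_se))
  invisible(x)
}
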