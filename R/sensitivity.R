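#' Cochran's Q heterogeneity test about the fixed-effect IVW estimate
#'
#' `Q = sum w_i (r_i - beta_ivw)^2` over per-instrument Wald ratios with
#' first-order weights `w_i = 1/se(r_i)^2` (equivalently the weighted residual
#' sum of squares about the origin-constrained regression); p from chi-square
#' on k - 1 degrees of freedom. `p > 0.05` is read as no heterogeneity.
#'
#' @param ivs A `harmonized_ivs` table with k >= 2 rows.
#' @return list with `q`, `df`, `p`.
#' @export
cochran_q <- function(ivs) {
  k <- nrow(ivs)
  stopifnot(k >= 2)
  wr <- wald_ratios(ivs)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  q <- sum(w * (wr$ratio - beta)^2)
  list(q = q, df = k - 1L, p = pchisq(q, k - 1, lower.tail = FALSE))
}

#' Rucker's Q heterogeneity test about the MR-Egger fit
#'
#' Weighted residual sum of squares about the Egger regression (same weights
#' as Cochran's Q); chi-square on k - 2 degrees of freedom. Because the Egger
#' fit nests the IVW fit, Rucker's Q never exceeds Cochran's Q.
#'
#' @param ivs A `harmonized_ivs` table with k >= 3 rows.
#' @return list with `q`, `df`, `p`.
#' @export
rucker_q <- function(ivs) {
  k <- nrow(ivs)
  stopifnot(k >= 3)
  fit <- mr_egger(ivs)
  if (!is.null(fit$extra$unavailable)) stop("rucker_q: ", fit$extra$unavailable)
  q <- fit$extra$q_rucker
  list(q = q, df = k - 2L, p = pchisq(q, k - 2, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional horizontal pleiotropy
#'
#' The intercept of the Egger regression and its t-test (k - 2 df); `p > 0.05`
#' is read as no horizontal pleiotropy.
#'
#' @param ivs A `harmonized_ivs` table with k >= 3 rows.
#' @return list with `estimate`, `se`, `p`.
#' @export
egger_intercept_test <- function(ivs) {
  fit <- mr_egger(ivs)
  if (!is.null(fit$extra$unavailable)) stop("egger_intercept_test: ", fit$extra$unavailable)
  list(estimate = fit$extra$intercept, se = fit$extra$intercept_se,
       p = fit$extra$intercept_p)
}

# leave-one-out fixed-effect IVW slopes for a matrix of simulated effects;
# bx, by are n_sim x k, w is length k. Returns the n_sim x k matrix of slopes
# computed without each column.
.loo_slopes_mat <- function(bx, by, w) {
  wm <- matrix(w, nrow(bx), length(w), byrow = TRUE)
  s1 <- rowSums(wm * bx * by)
  s2 <- rowSums(wm * bx^2)
  (s1 - wm * bx * by) / (s2 - wm * bx^2)
}

#' MR-PRESSO: global pleiotropy test, outlier test, distortion test
#'
#' The observed residual sum of squares of leave-one-out-predicted outcome
#' effects, `RSS = sum w_j (by_j - bx_j * beta_(-j))^2` with `w = 1/se_out^2`,
#' is compared against a parametric simulation null in which exposure and
#' outcome effects are redrawn around their leave-one-out predictions
#' (`n_sim` seeded draws); the global p is the null tail probability. Each
#' instrument's observed residual term is compared to its own simulated null:
#' Bonferroni-significant instruments are reported as outliers,
#' nominally-significant ones as potential outliers. The distortion test
#' compares the outlier-removed IVW estimate against estimates from random
#' same-size removals (two-sided); it is not applicable when no instrument is
#' flagged.
#'
#' @param ivs A `harmonized_ivs` table with k >= 4 rows.
#' @param n_sim Simulated null datasets (default 1000).
#' @param seed RNG seed.
#' @param sig Nominal significance level (default 0.05).
#' @return list with `available`, `global_rss`, `global_p`, `outliers`,
#'   `potential_outliers`, `outlier_stat` (observed per-SNP residual terms),
#'   `outlier_p` (per-SNP, Bonferroni-uncorrected), `distortion_p` (NA when
#'   not applicable).
#' @export
mr_presso <- function(ivs, n_sim = 1000, seed = 1, sig = 0.05) {
  k <- nrow(ivs)
  if (k < 4) {
    return(list(available = FALSE, reason = "needs at least 4 instruments",
                global_rss = NA_real_, global_p = NA_real_,
                outliers = character(0), potential_outliers = character(0),
                outlier_stat = setNames(numeric(0), character(0)),
                outlier_p = setNames(numeric(0), character(0)),
                distortion_p = NA_real_))
  }
  bx <- ivs$beta_exposure; by <- ivs$beta_outcome
  sx <- ivs$se_exposure; sy <- ivs$se_outcome
  w <- 1 / sy^2
  s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
  b_loo <- (s1 - w * bx * by) / (s2 - w * bx^2)
  obs_terms <- w * (by - b_loo * bx)^2
  obs_rss <- sum(obs_terms)

  with_seed(seed, {
    bx_m <- matrix(rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                         sd = rep(sx, each = n_sim)), n_sim, k)
    mu_y <- rep(b_loo * bx, each = n_sim)
    by_m <- matrix(rnorm(n_sim * k, mean = mu_y, sd = rep(sy, each = n_sim)), n_sim, k)
    bsim <- .loo_slopes_mat(bx_m, by_m, w)
    wm <- matrix(w, n_sim, k, byrow = TRUE)
    sim_terms <- wm * (by_m - bsim * bx_m)^2
    sim_rss <- rowSums(sim_terms)

    global_p <- (1 + sum(sim_rss >= obs_rss)) / (n_sim + 1)
    p_snp <- (1 + colSums(sim_terms >= matrix(obs_terms, n_sim, k, byrow = TRUE))) /
      (n_sim + 1)
    names(p_snp) <- ivs$snp_id
    outliers <- ivs$snp_id[p_snp < sig / k]
    potential <- setdiff(ivs$snp_id[p_snp < sig], outliers)

    distortion_p <- NA_real_
    flagged <- outliers
    if (length(flagged) > 0 && k - length(flagged) >= 2) {
      keep <- !(ivs$snp_id %in% flagged)
      beta_full <- sum(w * bx * by) / sum(w * bx^2)
      beta_nout <- sum((w * bx * by)[keep]) / sum((w * bx^2)[keep])
      d_obs <- beta_nout - beta_full
      n_rm <- length(flagged)
      d_null <- vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(k, n_rm)
        kp <- setdiff(seq_len(k), drop_idx)
        sum((w * bx * by)[kp]) / sum((w * bx^2)[kp]) - beta_full
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
    }
    list(available = TRUE, global_rss = obs_rss, global_p = global_p,
         outliers = outliers, potential_outliers = potential,
         outlier_stat = setNames(obs_terms, ivs$snp_id),
         outlier_p = p_snp, distortion_p = distortion_p)
  })
}

#' Leave-one-out influence analysis
#'
#' Refits the random-effects IVW estimate k times, omitting one instrument
#' each time. An instrument is influential iff omitting it flips the
#' significance status of the IVW p-value at `alpha` relative to the full-set
#' fit (in either direction) — the criterion under which removing a flagged
#' SNP changes the headline conclusion.
#'
#' @param ivs A `harmonized_ivs` table with k >= 3 rows.
#' @param alpha Significance level for the flip criterion (default 0.05).
#' @return list with `loo_table` (snp_id, beta_without, se_without, p_without;
#'   exactly k rows) and `influential_snps`.
#' @export
leave_one_out <- function(ivs, alpha = 0.05) {
  k <- nrow(ivs)
  stopifnot(k >= 3)
  full <- ivw_random_effects(ivs)
  sig_full <- full$p < alpha
  rows <- lapply(seq_len(k), function(j) {
    fit <- ivw_random_effects(ivs[-j, , drop = FALSE])
    data.frame(snp_id = ivs$snp_id[j], beta_without = fit$beta,
               se_without = fit$se, p_without = fit$p, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  influential <- loo$snp_id[(loo$p_without < alpha) != sig_full]
  list(loo_table = loo, influential_snps = influential)
}

#' Run the full sensitivity battery for one exposure-outcome pair
#'
#' Heterogeneity (Cochran's and Rucker's Q), directional pleiotropy (Egger
#' intercept), MR-PRESSO global/outlier/distortion tests, and leave-one-out
#' influence analysis.
#'
#' @param ivs A `harmonized_ivs` table.
#' @param n_sim MR-PRESSO simulated null datasets.
#' @param seed RNG seed for the stochastic tests.
#' @param alpha Significance level used throughout (default 0.05).
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(ivs, n_sim = 1000, seed = 1, alpha = 0.05) {
  k <- nrow(ivs)
  rep_ <- list(k = k,
               q_ivw = if (k >= 2) cochran_q(ivs) else NULL,
               q_rucker = if (k >= 3) rucker_q(ivs) else NULL,
               egger_intercept = if (k >= 3) egger_intercept_test(ivs) else NULL,
               presso = mr_presso(ivs, n_sim = n_sim, seed = seed, sig = alpha),
               loo = if (k >= 3) leave_one_out(ivs, alpha = alpha) else NULL)
  class(rep_) <- "sensitivity_report"
  rep_
}

#' Tabulate a sensitivity report (one row per exposure-outcome pair)
#'
#' @param rep A `sensitivity_report`.
#' @param exposure,outcome Labels for the row.
#' @return A one-row data.frame: Cochran p, Rucker p, Egger intercept p,
#'   distortion-test outlier count, PRESSO global p.
#' @export
sensitivity_table <- function(rep, exposure = "exposure", outcome = "outcome") {
  data.frame(exposure = exposure, outcome = outcome,
             cochran_q_p = rep$q_ivw$p %||% NA_real_,
             rucker_q_p = rep$q_rucker$p %||% NA_real_,
             egger_intercept_p = rep$egger_intercept$p %||% NA_real_,
             n_outliers = length(rep$presso$outliers),
             presso_global_p = rep$presso$global_p,
             stringsAsFactors = FALSE)
}
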