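test_that("Cochran's Q: zero for identical ratios, closed form for k = 2", {
  same <- make_ivs(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15))
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0)
  expect_equal(q0$p, 1)
  # ratios {0, 2} with unit ratio-SEs: beta = 1, Q = 1 + 1 = 2, df = 1
  ivs <- make_ivs(bx = c(1, 1), by = c(0, 2), se_y = c(1, 1))
  q <- cochran_q(ivs)
  expect_equal(q$q, 2)
  expect_equal(q$df, 1L)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE))
})

test_that("Rucker's Q: zero at an exact Egger fit, closed-form 3-SNP case", {
  bx <- c(0.1, 0.2, 0.4)
  exact <- make_ivs(bx, 0.1 + 0.5 * bx)
  expect_equal(rucker_q(exact)$q, 0, tolerance = 1e-20)
  # hand case: bx (1,2,3), by (1,2,4), unit weights -> residuals of the
  # ordinary least-squares line y = -2/3 + 1.5 x are (1/6, -1/3, 1/6)
  ivs <- make_ivs(bx = c(1, 2, 3), by = c(1, 2, 4), se_y = c(1, 1, 1))
  q <- rucker_q(ivs)
  expect_equal(q$q, (1 / 6)^2 + (1 / 3)^2 + (1 / 6)^2, tolerance = 1e-12)
  expect_equal(q$df, 1L)
})

test_that("Rucker's Q never exceeds Cochran's Q (nested fits, fuzzed)", {
  for (s in 1:25) {
    ivs <- random_ivs(sample(4:12, 1), 300 + s)
    expect_lte(rucker_q(ivs)$q, cochran_q(ivs)$q + 1e-9)
  }
})

test_that("Egger intercept test is consistent with the Egger fit", {
  ivs <- random_ivs(8, 9)
  t_ <- egger_intercept_test(ivs)
  fit <- mr_egger(ivs)
  expect_identical(t_$estimate, fit$extra$intercept)
  expect_identical(t_$p, fit$extra$intercept_p)
  shifted <- make_ivs(c(0.1, 0.2, 0.3, 0.5), 0.5 * c(0.1, 0.2, 0.3, 0.5) + 0.1)
  expect_equal(egger_intercept_test(shifted)$estimate, 0.1, tolerance = 1e-12)
})

test_that("PRESSO global statistic equals a brute-force RSS oracle on a 5-SNP fixture", {
  ivs <- random_ivs(5, 123)
  pr <- mr_presso(ivs, n_sim = 100, seed = 1)
  # oracle: for each SNP, IVW slope without it via lm, then the weighted RSS
  # of its leave-one-out prediction
  w <- 1 / ivs$se_outcome^2
  rss <- sum(sapply(seq_len(5), function(j) {
    b <- coef(lm(beta_outcome ~ 0 + beta_exposure, data = as.data.frame(ivs)[-j, ],
                 weights = w[-j]))
    w[j] * (ivs$beta_outcome[j] - b * ivs$beta_exposure[j])^2
  }))
  expect_equal(pr$global_rss, rss, tolerance = 1e-10)
})

test_that("a planted outlier is the unique PRESSO outlier; distortion test runs", {
  # shift chosen ~10 outcome-SEs: unambiguous for its own test, small enough
  # not to contaminate the other instruments' leave-one-out predictions
  ivs <- simulate_mr_dataset(mr_sim_spec(k_instruments = 15, beta_causal = 0.1,
                                         pleiotropy_mode = "outlier", n_outliers = 1,
                                         outlier_shift = 0.2, seed = 5))
  pr <- mr_presso(ivs, n_sim = 500, seed = 2)
  expect_identical(pr$outliers, attr(ivs, "truth")$outlier_snps)
  expect_lt(pr$global_p, 0.05)
  expect_false(is.na(pr$distortion_p))
  # clean set: distortion test not applicable
  clean <- simulate_mr_dataset(mr_sim_spec(k_instruments = 15, seed = 6))
  prc <- mr_presso(clean, n_sim = 500, seed = 2)
  expect_true(is.na(prc$distortion_p))
  expect_gt(prc$global_p, 0.05)
})

test_that("PRESSO below k = 4 reports unavailability; results reproducible under a seed", {
  small <- random_ivs(3, 1)
  pr <- mr_presso(small)
  expect_false(pr$available)
  ivs <- random_ivs(8, 55)
  a <- mr_presso(ivs, n_sim = 200, seed = 42)
  b <- mr_presso(ivs, n_sim = 200, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$global_p,
                         mr_presso(ivs, n_sim = 200, seed = 43)$global_p))
})

test_that("removing the top per-SNP PRESSO statistic strictly decreases the global RSS", {
  for (s in 1:10) {
    ivs <- random_ivs(8, 400 + s)
    pr <- mr_presso(ivs, n_sim = 50, seed = 1)
    worst <- names(which.max(pr$outlier_stat))
    sub <- new_harmonized_ivs(as.data.frame(ivs[ivs$snp_id != worst, ]))
    pr2 <- mr_presso(sub, n_sim = 50, seed = 1)
    expect_lt(pr2$global_rss, pr$global_rss)
  }
})

test_that("leave-one-out: exchangeable instruments flag nothing; table has k rows", {
  ivs <- make_ivs(bx = rep(0.2, 6), by = rep(0.1, 6))
  lo <- leave_one_out(ivs)
  expect_equal(nrow(lo$loo_table), 6L)
  expect_length(lo$influential_snps, 0)
})

test_that("leave-one-out flags exactly the instrument whose removal flips significance", {
  ivs <- influential_fixture()
  full <- ivw_random_effects(ivs)
  expect_lt(full$p, 0.05)
  lo <- leave_one_out(ivs)
  expect_identical(lo$influential_snps, "ivStrong")
  # verify by direct refits
  for (j in seq_len(nrow(ivs))) {
    refit <- ivw_random_effects(ivs[-j, , drop = FALSE])
    expect_identical(refit$p >= 0.05, ivs$snp_id[j] == "ivStrong")
    row <- lo$loo_table[lo$loo_table$snp_id == ivs$snp_id[j], ]
    expect_equal(row$beta_without, refit$beta)
    expect_equal(row$p_without, refit$p)
  }
})

test_that("sensitivity_report assembles the battery; its table row is well formed", {
  ivs <- random_ivs(10, 31)
  rep_ <- sensitivity_report(ivs, n_sim = 200, seed = 3)
  expect_s3_class(rep_, "sensitivity_report")
  tab <- sensitivity_table(rep_, "metabolite_x", "disease")
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("cochran_q_p", "rucker_q_p", "egger_intercept_p",
                    "n_outliers", "presso_global_p") %in% names(tab)))
  expect_equal(nrow(rep_$loo$loo_table), 10L)
})
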