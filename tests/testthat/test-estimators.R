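test_that("wald_ratio arithmetic and error on zero exposure effect", {
  row <- make_ivs(bx = 0.1, by = 0.2, se_y = 0.05)
  fit <- wald_ratio(row)
  expect_equal(fit$beta, 2)
  expect_equal(fit$se, 0.5)
  expect_equal(wald_ratio(make_ivs(bx = 0.1, by = 0))$beta, 0)
  expect_error(wald_ratio(make_ivs(bx = 0, by = 0.2)), "beta_exposure = 0")
})

test_that("first-order Wald SE agrees with a numeric delta-method oracle", {
  with_seed_test(4, {
    for (i in 1:10) {
      bx <- runif(1, 0.05, 0.4); by <- rnorm(1, 0.1, 0.2)
      sy <- runif(1, 0.01, 0.1)
      fit <- wald_ratio(make_ivs(bx, by, se_y = sy))
      # derivative of by/bx in by is 1/bx; numeric differentiation oracle
      h <- 1e-6
      d <- ((by + h) / bx - (by - h) / bx) / (2 * h)
      expect_equal(fit$se, abs(d) * sy, tolerance = 1e-8)
    }
  })
})

test_that("IVW: k = 1 falls back to the Wald ratio with a warning", {
  row <- make_ivs(bx = 0.2, by = 0.1, se_y = 0.05)
  expect_warning(fit <- ivw_random_effects(row), "Wald")
  w <- wald_ratio(row)
  expect_equal(fit$beta, w$beta)
  expect_equal(fit$se, w$se)
})

test_that("IVW: identical ratios give beta = ratio, Q = 0, scale 1", {
  ivs <- make_ivs(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.1, 0.2))
  fit <- ivw_random_effects(ivs)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$extra$q, 0)
  expect_equal(fit$extra$scale, 1)
  expect_equal(fit$se, fit$extra$se_fixed)
})

test_that("IVW and Egger match the weighted-least-squares oracle to 1e-10", {
  for (s in 1:20) {
    ivs <- random_ivs(8, s)
    w <- 1 / ivs$se_outcome^2

    fit <- ivw_random_effects(ivs)
    o <- wls_oracle(ivs$beta_exposure, ivs$beta_outcome, w, intercept = FALSE)
    expect_equal(fit$beta, unname(o$coef[1]), tolerance = 1e-10)
    expect_equal(fit$extra$q, o$rss, tolerance = 1e-10)
    expect_equal(fit$se, sqrt(o$cov_unscaled[1, 1]) * max(1, sqrt(o$rss / 7)),
                 tolerance = 1e-10)

    eg <- mr_egger(ivs)
    flip <- ifelse(ivs$beta_exposure < 0, -1, 1)
    oe <- wls_oracle(ivs$beta_exposure * flip, ivs$beta_outcome * flip, w)
    expect_equal(eg$beta, unname(oe$coef[2]), tolerance = 1e-10)
    expect_equal(eg$extra$intercept, unname(oe$coef[1]), tolerance = 1e-10)
    scale <- max(1, sqrt(oe$rss / (nrow(ivs) - 2)))
    expect_equal(eg$se, sqrt(oe$cov_unscaled[2, 2]) * scale, tolerance = 1e-10)
    expect_equal(eg$extra$intercept_se, sqrt(oe$cov_unscaled[1, 1]) * scale,
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact linear law and a constant pleiotropic shift", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  exact <- make_ivs(bx, 0.5 * bx)
  fe <- mr_egger(exact)
  expect_equal(fe$beta, 0.5, tolerance = 1e-12)
  expect_equal(fe$extra$intercept, 0, tolerance = 1e-12)

  shifted <- make_ivs(bx, 0.5 * bx + 0.1)
  fs <- mr_egger(shifted)
  expect_equal(fs$beta, 0.5, tolerance = 1e-12)
  expect_equal(fs$extra$intercept, 0.1, tolerance = 1e-12)

  expect_true(!is.null(mr_egger(make_ivs(c(0.1, 0.2), c(0.1, 0.1)))$extra$unavailable))
})

test_that("weighted median: plain median under equal weights, dominance rule", {
  ivs <- make_ivs(bx = c(1, 1, 1), by = c(1, 2, 9), se_y = c(1, 1, 1))
  expect_equal(weighted_median(ivs, n_boot = 50, seed = 1)$beta, 2)
  # one instrument holds > 50% of the weight -> its ratio is returned
  dom <- make_ivs(bx = c(1, 1, 1), by = c(1, 2, 9), se_y = c(0.1, 1, 1))
  expect_equal(weighted_median(dom, n_boot = 50, seed = 1)$beta, 1)
})

test_that("weighted median matches a cumulative-weight enumeration oracle", {
  oracle_wm <- function(r, w) {
    w <- w / sum(w)
    if (max(w) > 0.5) return(r[which.max(w)])
    o <- order(r); r <- r[o]; w <- w[o]
    s <- cumsum(w) - w / 2
    # walk the cumulative weights and interpolate across the 0.5 crossing
    i <- 1L
    while (s[i + 1] < 0.5) i <- i + 1L
    if (s[1] >= 0.5) return(r[1])
    r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
  }
  for (s in 1:20) {
    ivs <- random_ivs(9, 100 + s)
    fit <- weighted_median(ivs, n_boot = 10, seed = 1)
    r <- ivs$beta_outcome / ivs$beta_exposure
    w <- ivs$beta_exposure^2 / ivs$se_outcome^2
    expect_equal(fit$beta, oracle_wm(r, w), tolerance = 1e-12)
  }
})

test_that("mode estimators: majority cluster and weighted cluster selection", {
  ivs <- make_ivs(bx = rep(1, 4), by = c(1, 1.01, 0.99, 5), se_y = rep(0.5, 4))
  expect_lt(abs(simple_mode(ivs, n_boot = 50, seed = 1)$beta - 1), 0.2)
  # symmetric bimodal ratios; weights favour the upper cluster
  bim <- make_ivs(bx = rep(1, 6), by = c(0, 0.02, -0.02, 1, 1.02, 0.98),
                  se_y = c(1, 1, 1, 0.2, 0.2, 0.2))
  expect_lt(abs(weighted_mode(bim, n_boot = 50, seed = 1)$beta - 1), 0.2)
  expect_lt(abs(simple_mode(bim, n_boot = 50, seed = 1)$beta - 0.5), 0.6)
})

test_that("density mode matches a fine-grid brute-force kernel argmax", {
  for (s in 1:10) {
    ivs <- random_ivs(9, 200 + s)
    r <- ivs$beta_outcome / ivs$beta_exposure
    se_r <- ivs$se_outcome / abs(ivs$beta_exposure)
    k <- length(r)
    h <- 0.9 * min(sd(r), mad(r)) * k^(-0.2)
    fine <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 65536)
    coarse_step <- (max(r) - min(r) + 6 * h) / 4095

    dens_s <- colSums(dnorm(outer(r, fine, "-") / h))
    expect_lt(abs(simple_mode(ivs, n_boot = 5, seed = 1)$beta - fine[which.max(dens_s)]),
              coarse_step * 1.5)

    w <- (1 / se_r^2); w <- w / sum(w)
    dens_w <- colSums(w * dnorm(outer(r, fine, "-") / h))
    expect_lt(abs(weighted_mode(ivs, n_boot = 5, seed = 1)$beta - fine[which.max(dens_w)]),
              coarse_step * 1.5)
  }
})

test_that("all five estimators agree when every Wald ratio is identical", {
  bx <- c(0.1, -0.2, 0.3, 0.15, -0.4)
  ivs <- make_ivs(bx, 0.3 * bx)
  res <- mr_all(ivs, n_boot = 50, seed = 1)
  for (r in res) expect_equal(r$beta, 0.3, tolerance = 2e-3)
  expect_equal(res$ivw_re$beta, 0.3, tolerance = 1e-12)
  expect_equal(res$egger$beta, 0.3, tolerance = 1e-12)
  expect_equal(res$weighted_median$beta, 0.3, tolerance = 1e-12)
})

test_that("estimates are invariant to row order and to global sign flips", {
  ivs <- random_ivs(10, 77)
  perm <- ivs[sample(nrow(ivs)), , drop = FALSE]
  perm <- new_harmonized_ivs(as.data.frame(perm))
  expect_equal(ivw_random_effects(perm)$beta, ivw_random_effects(ivs)$beta)
  expect_equal(mr_egger(perm)$beta, mr_egger(ivs)$beta)
  expect_equal(weighted_median(perm, n_boot = 10, seed = 3)$beta,
               weighted_median(ivs, n_boot = 10, seed = 3)$beta)

  neg <- ivs
  neg$beta_exposure <- -neg$beta_exposure
  neg$beta_outcome <- -neg$beta_outcome
  neg <- new_harmonized_ivs(as.data.frame(neg))
  expect_equal(ivw_random_effects(neg)$beta, ivw_random_effects(ivs)$beta)
  expect_equal(mr_egger(neg)$beta, mr_egger(ivs)$beta)
  expect_equal(simple_mode(neg, n_boot = 5, seed = 2)$beta,
               simple_mode(ivs, n_boot = 5, seed = 2)$beta)
})

test_that("mr_result invariants: OR fields consistent with beta and CI", {
  fit <- ivw_random_effects(random_ivs(6, 5))
  expect_equal(fit$or_value, exp(fit$beta))
  expect_lt(fit$ci_low, fit$or_value)
  expect_gt(fit$ci_high, fit$or_value)
  tab <- mr_results_table(mr_all(random_ivs(8, 6), n_boot = 20, seed = 1))
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$method, c("ivw_re", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
})
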