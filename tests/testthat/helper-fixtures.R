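# fixtures built in code: no data files

# harmonized instrument set straight from effect vectors
make_ivs <- function(bx, by, se_x = rep(0.01, length(bx)), se_y = rep(0.05, length(bx)),
                     ids = sprintf("iv%03d", seq_along(bx))) {
  new_harmonized_ivs(data.frame(
    snp_id = ids,
    beta_exposure = bx, se_exposure = se_x,
    p_exposure = pmax(2 * pnorm(-abs(bx) / se_x), 1e-320),
    beta_outcome = by, se_outcome = se_y,
    p_outcome = pmax(2 * pnorm(-abs(by) / se_y), 1e-320),
    effect_allele = "A", other_allele = "G",
    stringsAsFactors = FALSE
  ))
}

# small sumstats table with controllable p-values / alleles / positions
make_sumstats <- function(n = 10, p = NULL, ea = NULL, oa = NULL,
                          chrom = "1", pos = NULL, beta = NULL, se = NULL,
                          ids = sprintf("rs%04d", seq_len(n)), nn = 10000) {
  df <- data.frame(
    snp_id = ids, chrom = chrom,
    pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
    effect_allele = if (is.null(ea)) rep("A", n) else ea,
    other_allele = if (is.null(oa)) rep("G", n) else oa,
    eaf = 0.3,
    beta = if (is.null(beta)) rep(0.1, n) else beta,
    se = if (is.null(se)) rep(0.02, n) else se,
    p = if (is.null(p)) rep(0.5, n) else p,
    n = nn, stringsAsFactors = FALSE
  )
  mrscreen:::new_sumstats(df)
}

# random instrument set for oracle comparisons
random_ivs <- function(k, seed) {
  with_seed_test(seed, {
    bx <- runif(k, 0.05, 0.3) * sample(c(-1, 1), k, TRUE)
    make_ivs(bx, 0.2 * bx + rnorm(k, 0, 0.03),
             se_x = runif(k, 0.005, 0.02), se_y = runif(k, 0.02, 0.08))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# the planted-influential fixture: one high-precision instrument alone carries
# IVW significance; every ratio is identical so heterogeneity stays at zero
influential_fixture <- function() {
  bx <- c(0.8, 0.9, 1.1, 1.2, 1.0)
  make_ivs(bx = bx, by = 0.1 * bx,
           se_x = rep(0.01, 5),
           se_y = c(0.15, 0.15, 0.15, 0.15, 0.03),
           ids = c("ivA", "ivB", "ivC", "ivD", "ivStrong"))
}

# weighted-least-squares oracle via the normal equations (independent of the
# package's sufficient-sum path)
wls_oracle <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtWX <- t(X) %*% (w * X)
  bhat <- solve(XtWX, t(X) %*% (w * y))
  list(coef = drop(bhat), cov_unscaled = solve(XtWX),
       rss = sum(w * (y - drop(X %*% bhat))^2))
}
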