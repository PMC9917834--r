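test_that("select_instruments thresholds strictly, empty result is not an error", {
  tab <- make_sumstats(n = 10, p = c(rep(0.5, 6), 1e-7, 4e-6, 2e-6, 4.9e-6))
  expect_equal(nrow(select_instruments(tab)), 4L)
  expect_equal(nrow(select_instruments(make_sumstats(n = 5, p = rep(0.5, 5)))), 0L)
  one <- make_sumstats(n = 5, p = c(0.5, 0.5, 1e-8, 0.5, 0.5))
  expect_equal(select_instruments(one)$snp_id, "rs0003")
})

test_that("clump keeps only the best SNP among linked candidates", {
  cand <- make_sumstats(n = 3, p = c(1e-6, 1e-8, 1e-7), pos = c(1000L, 2000L, 3000L))
  ld <- mrscreen:::new_ld_table(data.frame(
    snp_a = c("rs0001", "rs0001", "rs0002"),
    snp_b = c("rs0002", "rs0003", "rs0003"),
    r2 = c(0.5, 0.5, 0.5)))
  out <- clump(cand, ld)
  expect_equal(out$snp_id, "rs0002")  # smallest p wins
  expect_true(all(out$clump_seed))
  expect_equal(nrow(removals_ledger(out)), 2L)
})

test_that("identity LD keeps all candidates; missing pairs count as independent", {
  cand <- make_sumstats(n = 4, p = c(1e-8, 1e-7, 1e-6, 1e-9))
  expect_equal(nrow(clump(cand, NULL)), 4L)
  ld <- mrscreen:::new_ld_table(data.frame(snp_a = "rs0001", snp_b = "rs0002", r2 = 0))
  expect_equal(nrow(clump(cand, ld)), 4L)
})

test_that("clumping window boundary: SNPs 10,001 kb apart both survive", {
  cand <- make_sumstats(n = 2, p = c(1e-8, 1e-7), pos = c(1L, 10001001L))
  ld <- mrscreen:::new_ld_table(data.frame(snp_a = "rs0001", snp_b = "rs0002", r2 = 0.9))
  expect_equal(nrow(clump(cand, ld)), 2L)
  cand2 <- make_sumstats(n = 2, p = c(1e-8, 1e-7), pos = c(1L, 9999001L))
  expect_equal(clump(cand2, ld)$snp_id, "rs0001")
})

test_that("clump ties broken by snp_id for determinism", {
  cand <- make_sumstats(n = 2, p = c(1e-8, 1e-8), pos = c(1000L, 2000L),
                        ids = c("rsB", "rsA"))
  ld <- mrscreen:::new_ld_table(data.frame(snp_a = "rsB", snp_b = "rsA", r2 = 0.9))
  expect_equal(clump(cand, ld)$snp_id, "rsA")
})

test_that("outcome-associated instruments are excluded; missing ones dropped and logged", {
  ivs <- make_sumstats(n = 6, p = rep(1e-8, 6))
  outc <- make_sumstats(n = 5, p = c(1e-7, 1e-5, 0.5, 4e-6, 0.2),
                        ids = sprintf("rs%04d", 1:5))
  out <- exclude_outcome_associated(ivs, outc)
  expect_equal(out$snp_id, c("rs0002", "rs0003", "rs0005"))
  led <- removals_ledger(out)
  expect_equal(sum(led$reason == "missing in outcome"), 1L)
  expect_equal(sum(grepl("outcome p", led$reason)), 2L)
})

test_that("confounder blocklist removal is idempotent over duplicate entries", {
  ivs <- make_sumstats(n = 4)
  bl <- data.frame(snp_id = c("rs0002", "rs0002"), trait_label = c("smoking", "age"))
  out <- exclude_confounders(ivs, bl)
  expect_equal(nrow(out), 3L)
  expect_equal(nrow(removals_ledger(out)), 1L)
  expect_match(removals_ledger(out)$reason, "confounder")
  expect_identical(nrow(exclude_confounders(ivs, NULL)), 4L)
})

test_that("palindromic SNPs are dropped regardless of frequency", {
  ivs <- make_sumstats(n = 4, ea = c("A", "A", "C", "G"), oa = c("T", "G", "G", "C"))
  out <- drop_palindromic(ivs)
  expect_equal(out$snp_id, "rs0002")
  # 23-candidate fixture with 4 palindromic -> 19 survivors
  ea <- rep("A", 23); oa <- rep("G", 23)
  ea[c(2, 7, 11, 19)] <- c("A", "T", "C", "G"); oa[c(2, 7, 11, 19)] <- c("T", "A", "G", "C")
  out2 <- drop_palindromic(make_sumstats(n = 23, ea = ea, oa = oa))
  expect_equal(nrow(out2), 19L)
})

test_that("harmonize_alleles handles swap, strand complement and mismatch", {
  ex <- make_sumstats(n = 4, ea = c("A", "A", "A", "A"), oa = c("G", "G", "G", "G"),
                      beta = rep(0.2, 4), p = rep(1e-8, 4))
  outc <- make_sumstats(n = 4,
                        ea = c("A", "G", "T", "A"),
                        oa = c("G", "A", "C", "C"),
                        beta = c(0.3, 0.3, 0.3, 0.3), p = rep(0.5, 4))
  h <- harmonize_alleles(ex, outc)
  # rs1 same orientation, rs2 swapped -> negated, rs3 complement of (A,G) -> kept,
  # rs4 disjoint -> dropped
  expect_equal(h$snp_id, c("rs0001", "rs0002", "rs0003"))
  expect_equal(h$beta_outcome, c(0.3, -0.3, 0.3))
  expect_equal(h$flipped, c(FALSE, TRUE, FALSE))
  expect_equal(h$strand_flipped, c(FALSE, FALSE, TRUE))
  expect_equal(removals_ledger(h)$reason, "irreconcilable alleles")
  expect_true(all(h$beta_exposure == 0.2))
})

test_that("row-predicate filters commute; ledger counts always sum", {
  for (s in 1:8) {
    with_seed_test(s, {
      n <- 40
      ea <- sample(c("A", "C", "G", "T"), n, TRUE)
      oa <- sapply(ea, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1))
      tab <- make_sumstats(n = n, p = runif(n, 1e-9, 1e-4), ea = ea, oa = oa)
      outc <- make_sumstats(n = n, p = runif(n, 1e-7, 1))
      bl <- data.frame(snp_id = sample(tab$snp_id, 5), trait_label = "smoking")

      ord1 <- drop_palindromic(exclude_confounders(exclude_outcome_associated(
        select_instruments(tab, 1e-5), outc), bl))
      ord2 <- exclude_outcome_associated(drop_palindromic(exclude_confounders(
        select_instruments(tab, 1e-5), bl)), outc)
      expect_equal(sort(ord1$snp_id), sort(ord2$snp_id))

      led <- removals_ledger(ord1)
      cand <- select_instruments(tab, 1e-5)
      expect_equal(nrow(cand), nrow(ord1) + nrow(led))
    })
  }
})

test_that("build_instruments output satisfies the harmonized-set invariants", {
  sim <- simulate_gwas_pair(architecture_spec(n_snps = 8000, n_blocks = 160,
                                              h2_x = 0.5, rg = 0.4,
                                              n_x = 1e5, palindromic_frac = 0.2,
                                              seed = 31))
  ivs <- build_instruments(sim$exposure, sim$outcome, sim$ld_blocks)
  expect_s3_class(ivs, "harmonized_ivs")
  expect_false(any(mrscreen:::is_palindromic(ivs$effect_allele, ivs$other_allele)))
  expect_true(all(ivs$p_exposure < 5e-6))
  expect_true(all(ivs$se_exposure > 0 & ivs$se_outcome > 0))
  # clumped: at most one instrument per LD block
  blk <- sim$ld_blocks$block[match(ivs$snp_id, sim$ld_blocks$snp_id)]
  expect_false(any(duplicated(blk)))
})
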