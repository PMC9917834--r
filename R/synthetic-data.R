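#' Specify a bivariate polygenic architecture for the GWAS generator
#'
#' Captures the quantities LD score regression relates: per-trait SNP
#' heritability, genetic correlation, LD structure (equicorrelated blocks),
#' and the two GWAS sample sizes.
#'
#' @param n_snps Total SNP count M.
#' @param n_blocks Number of LD blocks (the last block may be short).
#' @param within_block_r2 Constant pairwise r-squared inside a block, in [0, 1].
#' @param h2_x,h2_y SNP heritabilities in [0, 1].
#' @param rg Genetic correlation in [-1, 1].
#' @param n_x,n_y GWAS sample sizes.
#' @param sample_overlap_frac Correlation of the two traits' estimation noise
#'   (shared samples inflate the cross-trait intercept, not the slope).
#' @param maf_range Interval in (0, 0.5] for uniform minor-allele frequencies.
#' @param palindromic_frac Expected fraction of A/T or C/G variants.
#' @param scale Effect-size convention of the emitted tables: `"linear"` or
#'   `"logor"` (labels the column semantics; the numbers are identical, as
#'   log odds ratios are the linear effects of a 0/1 outcome model).
#' @param seed Integer RNG seed; identical specs give identical output.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(n_snps = 20000, n_blocks = n_snps %/% 50,
                              within_block_r2 = 0.1,
                              h2_x = 0.3, h2_y = 0.3, rg = 0.5,
                              n_x = 50000, n_y = 50000,
                              sample_overlap_frac = 0,
                              maf_range = c(0.05, 0.5),
                              palindromic_frac = 0.16,
                              scale = c("linear", "logor"),
                              seed = 1) {
  scale <- match.arg(scale)
  check_field(is.numeric(n_snps) && n_snps >= 2, "n_snps", "must be a count >= 2")
  check_field(is.numeric(n_blocks) && n_blocks >= 1 && n_blocks <= n_snps,
              "n_blocks", "must be in [1, n_snps]")
  check_field(is.numeric(within_block_r2) && within_block_r2 >= 0 && within_block_r2 <= 1,
              "within_block_r2", "must lie in [0, 1]")
  check_field(is.numeric(h2_x) && h2_x >= 0 && h2_x <= 1, "h2_x", "must lie in [0, 1]")
  check_field(is.numeric(h2_y) && h2_y >= 0 && h2_y <= 1, "h2_y", "must lie in [0, 1]")
  check_field(is.numeric(rg) && rg >= -1 && rg <= 1, "rg", "must lie in [-1, 1]")
  check_field(is.numeric(n_x) && n_x > 0, "n_x", "must be positive")
  check_field(is.numeric(n_y) && n_y > 0, "n_y", "must be positive")
  check_field(is.numeric(sample_overlap_frac) && sample_overlap_frac >= 0 &&
                sample_overlap_frac <= 1, "sample_overlap_frac", "must lie in [0, 1]")
  check_field(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2], "maf_range", "must be an interval in (0, 0.5]")
  check_field(is.numeric(palindromic_frac) && palindromic_frac >= 0 &&
                palindromic_frac <= 1, "palindromic_frac", "must lie in [0, 1]")
  check_field(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")
  structure(list(n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
                 within_block_r2 = within_block_r2, h2_x = h2_x, h2_y = h2_y, rg = rg,
                 n_x = n_x, n_y = n_y, sample_overlap_frac = sample_overlap_frac,
                 maf_range = maf_range, palindromic_frac = palindromic_frac,
                 scale = scale, seed = as.integer(seed)),
            class = "architecture_spec")
}

.assign_alleles <- function(m, palindromic_frac) {
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  all_pairs <- expand.grid(a1 = ALLELES, a2 = ALLELES, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$a1 != all_pairs$a2, ]
  non_pal <- all_pairs[!is_palindromic(all_pairs$a1, all_pairs$a2), ]
  is_pal <- runif(m) < palindromic_frac
  out <- matrix(NA_character_, m, 2)
  if (any(is_pal)) {
    i <- sample.int(nrow(pal_pairs), sum(is_pal), replace = TRUE)
    out[is_pal, ] <- pal_pairs[i, ]
  }
  if (any(!is_pal)) {
    i <- sample.int(nrow(non_pal), sum(!is_pal), replace = TRUE)
    out[!is_pal, ] <- as.matrix(non_pal[i, ])
  }
  out
}

#' Simulate a pair of GWAS summary-statistics tables with known architecture
#'
#' Per-SNP true effects (standardized-genotype scale) are drawn bivariate
#' normal with per-SNP variance `h2 / M` and correlation `rg`. Marginal effects
#' mix true effects through equicorrelated LD blocks; z-scores add unit
#' estimation noise (correlated across traits by `sample_overlap_frac`);
#' reported effects are `z * se` with `se = 1 / sqrt(2 N maf (1 - maf))`
#' (per-allele scale), so the chi-square statistic `(beta/se)^2 = z^2` is
#' scale-free. LD scores are the row sums of block r-squared.
#'
#' @param spec An [architecture_spec()].
#' @return A list with elements `exposure` and `outcome` (`sumstats` tables),
#'   `ld` (an `ldscores` table with `m_total = n_snps`), `ld_blocks` (per-SNP
#'   block assignment with attribute `within_r2`), and `truth` (the spec).
#' @export
simulate_gwas_pair <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  m <- spec$n_snps
  with_seed(spec$seed, {
    # jittered block boundaries: sizes vary ~uniformly around m/n_blocks so LD
    # scores vary (constant sizes would make the LDSC regression singular),
    # while no block grows beyond ~1.4x the mean (keeps correlated units
    # smaller than a jackknife block, so block-jackknife SEs stay honest)
    nb <- spec$n_blocks
    if (nb > 1) {
      base <- m / nb
      cuts <- round(seq_len(nb - 1) * base + runif(nb - 1, -0.4, 0.4) * base)
      cuts <- pmin(pmax(cuts, 1L), m - 1L)
      for (i in seq_along(cuts)[-1]) cuts[i] <- max(cuts[i], cuts[i - 1] + 1L)
      cuts <- pmin(cuts, (m - 1L) - (length(cuts) - seq_along(cuts)))
      for (i in rev(seq_along(cuts))[-1]) cuts[i] <- min(cuts[i], cuts[i + 1] - 1L)
      sizes <- diff(c(0L, cuts, m))
    } else sizes <- m
    block <- rep(seq_len(nb), times = sizes)
    block_size <- as.vector(table(block))[block]
    r <- sqrt(spec$within_block_r2)

    sx <- sqrt(spec$h2_x / m)
    sy <- sqrt(spec$h2_y / m)
    u1 <- rnorm(m)
    u2 <- rnorm(m)
    bx <- sx * u1
    by <- sy * (spec$rg * u1 + sqrt(1 - spec$rg^2) * u2)

    # marginal effect_j = beta_j + r * sum_{k != j in block} beta_k
    bsum_x <- ave(bx, block, FUN = sum)
    bsum_y <- ave(by, block, FUN = sum)
    mx <- bx + r * (bsum_x - bx)
    my <- by + r * (bsum_y - by)

    ell <- 1 + (block_size - 1) * spec$within_block_r2

    e1 <- rnorm(m)
    e2 <- rnorm(m)
    rho <- spec$sample_overlap_frac
    ex <- e1
    ey <- rho * e1 + sqrt(1 - rho^2) * e2
    zx <- sqrt(spec$n_x) * mx + ex
    zy <- sqrt(spec$n_y) * my + ey

    maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
    se_x <- 1 / sqrt(2 * spec$n_x * maf * (1 - maf))
    se_y <- 1 / sqrt(2 * spec$n_y * maf * (1 - maf))
    alle <- .assign_alleles(m, spec$palindromic_frac)

    base <- data.frame(
      snp_id = sprintf("rs%07d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * 5000L,
      effect_allele = alle[, 1],
      other_allele = alle[, 2],
      eaf = maf,
      stringsAsFactors = FALSE
    )
    mk <- function(z, se, n) {
      df <- base
      df$beta <- z * se
      df$se <- se
      df$p <- pmax(2 * pnorm(-abs(z)), 1e-320)
      df$n <- n
      new_sumstats(df)
    }
    ld <- new_ldscores(data.frame(snp_id = base$snp_id, ldscore = ell,
                                  stringsAsFactors = FALSE), m)
    blocks <- data.frame(snp_id = base$snp_id, block = block, stringsAsFactors = FALSE)
    class(blocks) <- c("ld_blocks", "data.frame")
    attr(blocks, "within_r2") <- spec$within_block_r2
    list(exposure = mk(zx, se_x, spec$n_x),
         outcome = mk(zy, se_y, spec$n_y),
         ld = ld, ld_blocks = blocks, truth = spec)
  })
}

#' Simulate a panel of exposures sharing one outcome trait
#'
#' Generates the outcome once, then each exposure's true effects with its own
#' genetic correlation against the shared outcome, on a common set of variants
#' and LD structure — the layout of a metabolite-panel screen against a single
#' disease GWAS.
#'
#' @param spec An [architecture_spec()]; `h2_x`/`n_x` apply to every exposure
#'   and `rg` is ignored in favour of `rg_panel`.
#' @param rg_panel Numeric vector of genetic correlations, one per exposure.
#' @return A list with `exposures` (named list of `sumstats`), `outcome`,
#'   `ld`, `ld_blocks`, and `truth` (the per-exposure rg vector).
#' @export
simulate_gwas_panel <- function(spec, rg_panel) {
  stopifnot(inherits(spec, "architecture_spec"), all(abs(rg_panel) <= 1))
  m <- spec$n_snps
  with_seed(spec$seed, {
    nb <- spec$n_blocks
    if (nb > 1) {
      base <- m / nb
      cuts <- round(seq_len(nb - 1) * base + runif(nb - 1, -0.4, 0.4) * base)
      cuts <- pmin(pmax(cuts, 1L), m - 1L)
      for (i in seq_along(cuts)[-1]) cuts[i] <- max(cuts[i], cuts[i - 1] + 1L)
      cuts <- pmin(cuts, (m - 1L) - (length(cuts) - seq_along(cuts)))
      for (i in rev(seq_along(cuts))[-1]) cuts[i] <- min(cuts[i], cuts[i + 1] - 1L)
      sizes <- diff(c(0L, cuts, m))
    } else sizes <- m
    block <- rep(seq_len(nb), times = sizes)
    block_size <- as.vector(table(block))[block]
    r <- sqrt(spec$within_block_r2)
    ell <- 1 + (block_size - 1) * spec$within_block_r2
    maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
    alle <- .assign_alleles(m, spec$palindromic_frac)
    base_df <- data.frame(snp_id = sprintf("rs%07d", seq_len(m)), chrom = "1",
                          pos = seq_len(m) * 5000L, effect_allele = alle[, 1],
                          other_allele = alle[, 2], eaf = maf,
                          stringsAsFactors = FALSE)
    mk <- function(u, h2, n, noise) {
      b <- sqrt(h2 / m) * u
      marg <- b + r * (ave(b, block, FUN = sum) - b)
      z <- sqrt(n) * marg + noise
      se <- 1 / sqrt(2 * n * maf * (1 - maf))
      df <- base_df
      df$beta <- z * se; df$se <- se
      df$p <- pmax(2 * pnorm(-abs(z)), 1e-320)
      df$n <- n
      new_sumstats(df)
    }
    uy <- rnorm(m)
    ey <- rnorm(m)
    outcome <- mk(uy, spec$h2_y, spec$n_y, ey)
    rho <- spec$sample_overlap_frac
    exposures <- lapply(rg_panel, function(rg_i) {
      ui <- rg_i * uy + sqrt(1 - rg_i^2) * rnorm(m)
      ei <- rho * ey + sqrt(1 - rho^2) * rnorm(m)
      mk(ui, spec$h2_x, spec$n_x, ei)
    })
    names(exposures) <- sprintf("metab_%02d", seq_along(rg_panel))
    ld <- new_ldscores(data.frame(snp_id = base_df$snp_id, ldscore = ell,
                                  stringsAsFactors = FALSE), m)
    blocks <- data.frame(snp_id = base_df$snp_id, block = block, stringsAsFactors = FALSE)
    class(blocks) <- c("ld_blocks", "data.frame")
    attr(blocks, "within_r2") <- spec$within_block_r2
    list(exposures = exposures, outcome = outcome, ld = ld, ld_blocks = blocks,
         truth = list(rg_panel = setNames(rg_panel, names(exposures))))
  })
}

#' Specify a simulated Mendelian-randomization instrument set
#'
#' @param k_instruments Number of instruments (>= 1).
#' @param beta_causal True causal effect of the exposure on the outcome.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (mean-zero direct
#'   effects), `"directional"` (mean-shifted direct effects), `"outlier"`
#'   (a few instruments receive a large direct-effect shift).
#' @param pleiotropy_sd Scale of the pleiotropic direct effects.
#' @param n_outliers Number of planted outliers (`outlier` mode), < k.
#' @param outlier_shift Direct-effect shift added to each planted outlier.
#' @param exposure_se_range,outcome_se_range Uniform ranges for per-instrument
#'   standard errors.
#' @param palindromic_frac Expected fraction of A/T or C/G instruments.
#' @param seed Integer RNG seed.
#' @return An `mr_sim_spec` list.
#' @export
mr_sim_spec <- function(k_instruments = 30, beta_causal = 0.1,
                        pleiotropy_mode = c("none", "balanced", "directional", "outlier"),
                        pleiotropy_sd = 0.01, n_outliers = 0, outlier_shift = 0.1,
                        exposure_se_range = c(0.005, 0.015),
                        outcome_se_range = c(0.01, 0.03),
                        palindromic_frac = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  check_field(is.numeric(k_instruments) && k_instruments >= 1,
              "k_instruments", "must be a count >= 1")
  check_field(is.numeric(beta_causal) && is.finite(beta_causal),
              "beta_causal", "must be finite")
  check_field(is.numeric(n_outliers) && n_outliers >= 0 && n_outliers < k_instruments,
              "n_outliers", "must satisfy 0 <= n_outliers < k_instruments")
  check_field(length(exposure_se_range) == 2 && all(exposure_se_range > 0) &&
                diff(exposure_se_range) >= 0, "exposure_se_range", "must be a positive interval")
  check_field(length(outcome_se_range) == 2 && all(outcome_se_range > 0) &&
                diff(outcome_se_range) >= 0, "outcome_se_range", "must be a positive interval")
  check_field(is.numeric(palindromic_frac) && palindromic_frac >= 0 &&
                palindromic_frac <= 1, "palindromic_frac", "must lie in [0, 1]")
  check_field(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")
  structure(list(k_instruments = as.integer(k_instruments), beta_causal = beta_causal,
                 pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
                 n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
                 exposure_se_range = exposure_se_range,
                 outcome_se_range = outcome_se_range,
                 palindromic_frac = palindromic_frac, seed = as.integer(seed)),
            class = "mr_sim_spec")
}

#' Simulate a harmonized instrument set with known causal ground truth
#'
#' Exposure effects are drawn away from zero (instrument relevance); the
#' outcome effect of each instrument is `beta_causal * bx_true` plus a
#' pleiotropy term per mode plus estimation noise. In `outlier` mode,
#' `outlier_shift` is added to `n_outliers` randomly chosen instruments, which
#' are recorded in the ground truth.
#'
#' @param spec An [mr_sim_spec()].
#' @return A `harmonized_ivs` table whose `truth` attribute records
#'   `beta_causal`, `pleiotropy_mode`, the planted `outlier_snps`, and the
#'   true per-instrument exposure effects.
#' @export
simulate_mr_dataset <- function(spec) {
  stopifnot(inherits(spec, "mr_sim_spec"))
  k <- spec$k_instruments
  with_seed(spec$seed, {
    bx_true <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.05, 0.25)
    se_x <- runif(k, spec$exposure_se_range[1], spec$exposure_se_range[2])
    se_y <- runif(k, spec$outcome_se_range[1], spec$outcome_se_range[2])
    pleio <- switch(spec$pleiotropy_mode,
      none = rep(0, k),
      balanced = rnorm(k, 0, spec$pleiotropy_sd),
      directional = rnorm(k, spec$pleiotropy_sd, spec$pleiotropy_sd / 2),
      outlier = rep(0, k)
    )
    outlier_idx <- integer(0)
    if (spec$pleiotropy_mode == "outlier" && spec$n_outliers > 0) {
      outlier_idx <- sort(sample.int(k, spec$n_outliers))
      pleio[outlier_idx] <- pleio[outlier_idx] + spec$outlier_shift
    }
    by_true <- spec$beta_causal * bx_true + pleio
    bx <- bx_true + rnorm(k) * se_x
    by <- by_true + rnorm(k) * se_y
    alle <- .assign_alleles(k, spec$palindromic_frac)
    ids <- sprintf("iv%03d", seq_len(k))
    ivs <- new_harmonized_ivs(data.frame(
      snp_id = ids,
      beta_exposure = bx, se_exposure = se_x,
      p_exposure = pmax(2 * pnorm(-abs(bx) / se_x), 1e-320),
      beta_outcome = by, se_outcome = se_y,
      p_outcome = pmax(2 * pnorm(-abs(by) / se_y), 1e-320),
      effect_allele = alle[, 1], other_allele = alle[, 2],
      clump_seed = TRUE, flipped = FALSE, strand_flipped = FALSE,
      stringsAsFactors = FALSE
    ), exposure_label = "simulated_exposure", outcome_label = "simulated_outcome",
    check_palindromic = FALSE)
    attr(ivs, "truth") <- list(beta_causal = spec$beta_causal,
                               pleiotropy_mode = spec$pleiotropy_mode,
                               outlier_snps = ids[outlier_idx],
                               bx_true = bx_true)
    ivs
  })
}
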