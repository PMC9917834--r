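#' Harmonized instrument-set constructor
#'
#' The unit of all MR computation: joined exposure/outcome effects on a common
#' effect-allele orientation, with per-row provenance flags and a removals
#' ledger accumulated by the selection filters.
#'
#' @param df data.frame with columns `snp_id`, `beta_exposure`, `se_exposure`,
#'   `p_exposure`, `beta_outcome`, `se_outcome`, `p_outcome`, `effect_allele`,
#'   `other_allele` (plus optional provenance flags).
#' @param exposure_label,outcome_label Trait labels.
#' @param removals Removals ledger (data.frame `snp_id`, `stage`, `reason`).
#' @param check_palindromic Enforce the no-palindromic-rows invariant.
#' @return A `harmonized_ivs` data.frame.
#' @export
new_harmonized_ivs <- function(df, exposure_label = "exposure",
                               outcome_label = "outcome",
                               removals = empty_removals(),
                               check_palindromic = TRUE) {
  need <- c("snp_id", "beta_exposure", "se_exposure", "p_exposure",
            "beta_outcome", "se_outcome", "p_outcome",
            "effect_allele", "other_allele")
  stopifnot(all(need %in% names(df)))
  for (fl in c("clump_seed", "flipped", "strand_flipped")) {
    if (is.null(df[[fl]])) df[[fl]] <- if (fl == "clump_seed") TRUE else FALSE
  }
  if (nrow(df)) {
    stopifnot(all(df$se_exposure > 0), all(df$se_outcome > 0))
    if (check_palindromic && any(is_palindromic(df$effect_allele, df$other_allele))) {
      stop("harmonized_ivs: palindromic rows are not allowed")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("harmonized_ivs", "data.frame"),
            exposure_label = exposure_label, outcome_label = outcome_label,
            removals = removals)
}

empty_removals <- function() {
  data.frame(snp_id = character(0), stage = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

log_removals <- function(x, ids, stage, reason) {
  if (!length(ids)) return(x)
  led <- attr(x, "removals") %||% empty_removals()
  add <- data.frame(snp_id = ids, stage = stage, reason = reason,
                    stringsAsFactors = FALSE)
  attr(x, "removals") <- rbind(led, add)
  x
}

#' Removals ledger of an instrument set
#' @param x An object carrying a `removals` attribute.
#' @return data.frame with columns `snp_id`, `stage`, `reason`.
#' @export
removals_ledger <- function(x) attr(x, "removals") %||% empty_removals()

#' Select candidate instruments by exposure p-value
#'
#' Keeps rows with exposure association p below the genome-wide-suggestive
#' threshold (default 5e-6). An empty result is an explicit outcome, not an
#' error.
#'
#' @param exposure A `sumstats` table.
#' @param p_thresh Exposure p-value threshold.
#' @return The surviving subset (still a `sumstats` table).
#' @export
select_instruments <- function(exposure, p_thresh = 5e-6) {
  stopifnot(inherits(exposure, "sumstats"))
  out <- exposure[exposure$p < p_thresh, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_sumstats(out)
  attr(out, "removals") <- empty_removals()
  out
}

# pairwise r2 matrix for a set of SNP ids, from either an ld_table (long
# pairs; missing pairs are r2 = 0) or an ld_blocks assignment (equicorrelated
# within block).
ld_r2_matrix <- function(ld, ids) {
  n <- length(ids)
  r2 <- diag(1, n)
  dimnames(r2) <- list(ids, ids)
  if (n < 2) return(r2)
  if (inherits(ld, "ld_blocks")) {
    blk <- ld$block[match(ids, ld$snp_id)]
    same <- outer(blk, blk, "==")
    same[is.na(same)] <- FALSE
    r2[same] <- attr(ld, "within_r2")
    diag(r2) <- 1
  } else if (inherits(ld, "ld_table")) {
    ia <- match(ld$snp_a, ids)
    ib <- match(ld$snp_b, ids)
    keep <- !is.na(ia) & !is.na(ib)
    r2[cbind(ia[keep], ib[keep])] <- ld$r2[keep]
    r2[cbind(ib[keep], ia[keep])] <- ld$r2[keep]
  } else if (is.null(ld)) {
    # no LD information: treat all pairs as independent
  } else stop("unsupported LD object; expected ld_table or ld_blocks")
  r2
}

#' Greedy LD clumping of candidate instruments
#'
#' Candidates are visited in order of ascending p-value (ties broken by SNP id
#' for determinism). A candidate within `window_kb` of an already selected SNP
#' on the same chromosome with r-squared at or above `r2_thresh` is removed;
#' pairs absent from the LD table are treated as independent. Selected SNPs
#' are flagged as clump seeds.
#'
#' @param candidates A `sumstats` table (typically from [select_instruments()]).
#' @param ld An `ld_table`, `ld_blocks`, or NULL (no LD, keep everything).
#' @param r2_thresh Pruning threshold on r-squared (default 0.001).
#' @param window_kb Clumping distance in kilobases (default 10,000 kb).
#' @return The pruned `sumstats` table with a `clump_seed` column.
#' @export
clump <- function(candidates, ld = NULL, r2_thresh = 0.001, window_kb = 10000) {
  x <- candidates
  if (nrow(x) < 2) {
    x$clump_seed <- rep(TRUE, nrow(x))
    return(x)
  }
  ord <- order(x$p, x$snp_id)
  r2 <- ld_r2_matrix(ld, x$snp_id)
  keep <- logical(nrow(x))
  for (i in ord) {
    sel <- which(keep)
    if (!length(sel)) { keep[i] <- TRUE; next }
    near <- x$chrom[sel] == x$chrom[i] &
      abs(x$pos[sel] - x$pos[i]) <= window_kb * 1000
    linked <- near & r2[sel, i] >= r2_thresh
    if (!any(linked)) keep[i] <- TRUE
  }
  dropped <- x$snp_id[!keep]
  out <- x[keep, , drop = FALSE]
  out$clump_seed <- TRUE
  rownames(out) <- NULL
  out <- new_sumstats(out)
  attr(out, "removals") <- attr(x, "removals") %||% empty_removals()
  log_removals(out, dropped, "clump", "in LD with a better-ranked instrument")
}

#' Exclude instruments associated with the outcome
#'
#' Removes instruments whose outcome-GWAS p-value is below `p_thresh`
#' (they violate the exclusion-restriction screen); instruments absent from
#' the outcome table are dropped with a "missing in outcome" log entry.
#'
#' @param ivs Candidate `sumstats` table (exposure rows).
#' @param outcome A `sumstats` table for the outcome trait.
#' @param p_thresh Outcome p-value threshold (default 5e-6).
#' @return Filtered table; removals appended to the ledger.
#' @export
exclude_outcome_associated <- function(ivs, outcome, p_thresh = 5e-6) {
  i <- match(ivs$snp_id, outcome$snp_id)
  missing <- is.na(i)
  assoc <- !missing & outcome$p[i] < p_thresh
  out <- ivs[!missing & !assoc, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_sumstats(out)
  attr(out, "removals") <- attr(ivs, "removals") %||% empty_removals()
  out <- log_removals(out, ivs$snp_id[missing], "outcome_exclusion", "missing in outcome")
  log_removals(out, ivs$snp_id[assoc], "outcome_exclusion",
               sprintf("outcome p < %g", p_thresh))
}

#' Exclude instruments listed in a confounder blocklist
#'
#' Local stand-in for database screening of instruments against known
#' confounder traits; rows whose SNP id appears in the blocklist are removed
#' and the matched trait label is logged. Duplicate blocklist entries cause a
#' single removal.
#'
#' @param ivs Candidate `sumstats` table.
#' @param blocklist A `blocklist` data.frame (or NULL for no screening).
#' @return Filtered table; removals appended to the ledger.
#' @export
exclude_confounders <- function(ivs, blocklist = NULL) {
  if (is.null(blocklist) || nrow(blocklist) == 0) return(ivs)
  i <- match(ivs$snp_id, blocklist$snp_id)
  hit <- !is.na(i)
  out <- ivs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_sumstats(out)
  attr(out, "removals") <- attr(ivs, "removals") %||% empty_removals()
  log_removals(out, ivs$snp_id[hit], "confounder_exclusion",
               sprintf("confounder: %s", blocklist$trait_label[i[hit]]))
}

#' Drop palindromic (A/T, C/G) instruments
#'
#' Palindromic variants are removed outright, regardless of allele frequency,
#' because their strand cannot be resolved from the alleles alone.
#'
#' @param ivs Candidate table with `effect_allele` / `other_allele` columns.
#' @return Filtered table; removals appended to the ledger.
#' @export
drop_palindromic <- function(ivs) {
  pal <- is_palindromic(ivs$effect_allele, ivs$other_allele)
  out <- ivs[!pal, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ivs)
  attr(out, "removals") <- attr(ivs, "removals") %||% empty_removals()
  for (a in c("exposure_label", "outcome_label", "truth")) {
    if (!is.null(attr(ivs, a))) attr(out, a) <- attr(ivs, a)
  }
  log_removals(out, ivs$snp_id[pal], "palindromic", "palindromic alleles")
}

#' Harmonize outcome effects onto the exposure allele orientation
#'
#' For each shared SNP: if the outcome alleles match the exposure alleles the
#' row is kept as is; if they are swapped, the outcome effect is negated; if
#' they are the strand complement (same or swapped order) they are
#' complemented first; irreconcilable rows are dropped and logged.
#'
#' @param exposure_rows Candidate `sumstats` rows for the exposure.
#' @param outcome A `sumstats` table for the outcome.
#' @param exposure_label,outcome_label Trait labels for the result.
#' @return A `harmonized_ivs` table.
#' @export
harmonize_alleles <- function(exposure_rows, outcome,
                              exposure_label = "exposure",
                              outcome_label = "outcome") {
  i <- match(exposure_rows$snp_id, outcome$snp_id)
  present <- !is.na(i)
  ex <- exposure_rows[present, , drop = FALSE]
  oc <- outcome[i[present], , drop = FALSE]

  same <- oc$effect_allele == ex$effect_allele & oc$other_allele == ex$other_allele
  swap <- oc$effect_allele == ex$other_allele & oc$other_allele == ex$effect_allele
  comp_same <- complement_allele(oc$effect_allele) == ex$effect_allele &
    complement_allele(oc$other_allele) == ex$other_allele
  comp_swap <- complement_allele(oc$effect_allele) == ex$other_allele &
    complement_allele(oc$other_allele) == ex$effect_allele
  ok <- same | swap | comp_same | comp_swap
  flip <- (swap | comp_swap) & ok

  df <- data.frame(
    snp_id = ex$snp_id,
    beta_exposure = ex$beta, se_exposure = ex$se, p_exposure = ex$p,
    beta_outcome = ifelse(flip, -oc$beta, oc$beta),
    se_outcome = oc$se, p_outcome = oc$p,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    clump_seed = if (!is.null(ex$clump_seed)) ex$clump_seed else TRUE,
    flipped = flip,
    strand_flipped = (comp_same | comp_swap) & ok,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]

  removals <- attr(exposure_rows, "removals") %||% empty_removals()
  out <- new_harmonized_ivs(df, exposure_label, outcome_label, removals,
                            check_palindromic = FALSE)
  out <- log_removals(out, exposure_rows$snp_id[!present], "harmonize", "missing in outcome")
  log_removals(out, ex$snp_id[!ok], "harmonize", "irreconcilable alleles")
}

#' Full instrument screen: threshold, clump, exclusions, harmonization
#'
#' Applies the five-step screen in its canonical order — exposure p-value
#' threshold, greedy LD clumping, outcome-association exclusion, confounder
#' blocklist exclusion, palindromic drop — then harmonizes alleles against the
#' outcome table.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param ld LD information for clumping (`ld_table`, `ld_blocks`, or NULL).
#' @param blocklist Optional confounder `blocklist`.
#' @param exposure_p,outcome_p P-value thresholds (defaults 5e-6).
#' @param clump_r2,clump_kb Clumping parameters (defaults 0.001, 10,000 kb).
#' @param exposure_label,outcome_label Trait labels.
#' @return A `harmonized_ivs` table (possibly with zero rows).
#' @export
build_instruments <- function(exposure, outcome, ld = NULL, blocklist = NULL,
                              exposure_p = 5e-6, outcome_p = 5e-6,
                              clump_r2 = 0.001, clump_kb = 10000,
                              exposure_label = "exposure", outcome_label = "outcome") {
  x <- select_instruments(exposure, exposure_p)
  x <- clump(x, ld, clump_r2, clump_kb)
  x <- exclude_outcome_associated(x, outcome, outcome_p)
  x <- exclude_confounders(x, blocklist)
  x <- drop_palindromic(x)
  harmonize_alleles(x, outcome, exposure_label, outcome_label)
}
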