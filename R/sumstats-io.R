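#' @importFrom stats pnorm pchisq pt qnorm mad sd dnorm rnorm runif setNames ave var
#' @importFrom utils head
NULL

ALLELES <- c("A", "C", "G", "T")

# header synonyms recognised by read_sumstats (all matching is case-insensitive)
.SUMSTATS_SYNONYMS <- list(
  snp_id        = c("snp_id", "snp", "rsid", "rs_id", "variant_id", "markername", "id"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1", "alt"),
  other_allele  = c("other_allele", "a2", "oa", "allele2", "allele0", "ref"),
  eaf           = c("eaf", "freq", "af", "effect_allele_frequency", "frq"),
  beta          = c("beta", "b", "effect", "es"),
  or_col        = c("or", "odds_ratio"),
  se            = c("se", "stderr", "standard_error"),
  p             = c("p", "pval", "p_value", "pvalue", "p_bolt_lmm"),
  n             = c("n", "samplesize", "sample_size", "n_total", "neff")
)

# fread with transparent gzip support (no R.utils dependency): connections
# auto-decompress, so .gz files are routed through readLines
.fread_auto <- function(path, skip = 0L) {
  if (grepl("\\.gz$", path)) {
    lines <- readLines(gzfile(path))
    if (skip > 0L) lines <- lines[-seq_len(skip)]
    data.table::fread(text = lines, data.table = FALSE, showProgress = FALSE)
  } else {
    data.table::fread(path, data.table = FALSE, showProgress = FALSE, skip = skip)
  }
}

.read_first_line <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  readLines(con, n = 1L)
}

new_sumstats <- function(df) {
  stopifnot(is.data.frame(df))
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Validate a summary-statistics table, dropping invalid rows
#'
#' Rows violating the type invariants (non-positive or non-finite SE, p outside
#' (0, 1], identical or non-ACGT alleles, non-finite effect, duplicated SNP id)
#' are removed and the number of drops is reported via `message()` and stored in
#' the `n_dropped` attribute.
#'
#' @param df data.frame with the internal sumstats columns.
#' @return A validated `sumstats` object.
#' @keywords internal
validate_sumstats <- function(df) {
  n0 <- nrow(df)
  ok <- is.finite(df$se) & df$se > 0 &
    is.finite(df$p) & df$p > 0 & df$p <= 1 &
    is.finite(df$beta) &
    df$effect_allele %in% ALLELES & df$other_allele %in% ALLELES &
    df$effect_allele != df$other_allele
  ok[is.na(ok)] <- FALSE
  df <- df[ok, , drop = FALSE]
  df <- df[!duplicated(df$snp_id), , drop = FALSE]
  dropped <- n0 - nrow(df)
  if (dropped > 0L) {
    message(sprintf("read_sumstats: dropped %d row(s) violating invariants", dropped))
  }
  rownames(df) <- NULL
  out <- new_sumstats(df)
  attr(out, "n_dropped") <- dropped
  out
}

#' Read GWAS summary statistics from a delimited text file
#'
#' The delimiter is auto-detected (tab, comma or whitespace) and gzip files are
#' transparently decompressed. Common header synonyms are recognised
#' (SNP/rsid/variant_id, A1/effect_allele, BETA/b, OR, SE, P/pval, EAF/freq, N);
#' `column_map` overrides the automatic mapping. Odds ratios are converted to
#' the log scale, with the SE column taken as the SE of the log odds ratio.
#' Rows violating the table invariants are dropped with a logged count.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping internal names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `or_col`, `se`, `p`, `n`) to header names in the file.
#' @return A `sumstats` data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  raw <- .fread_auto(path)
  hdr <- tolower(names(raw))
  pick <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) {
      i <- match(tolower(column_map[[field]]), hdr)
      if (is.na(i)) stop(sprintf("column_map names '%s' for '%s' but the file has no such column",
                                 column_map[[field]], field))
      return(i)
    }
    i <- match(.SUMSTATS_SYNONYMS[[field]], hdr)
    i <- i[!is.na(i)]
    if (length(i)) i[1] else NA_integer_
  }
  idx <- vapply(names(.SUMSTATS_SYNONYMS), pick, integer(1))
  mandatory <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "se", "p")
  missing <- mandatory[is.na(idx[mandatory])]
  if (is.na(idx[["beta"]]) && is.na(idx[["or_col"]])) missing <- c(missing, "beta (or OR)")
  if (length(missing)) {
    stop("read_sumstats: cannot map mandatory column(s): ", paste(missing, collapse = ", "))
  }
  col <- function(field, default = NA_real_) {
    if (is.na(idx[[field]])) rep(default, nrow(raw)) else raw[[idx[[field]]]]
  }
  beta <- if (!is.na(idx[["beta"]])) as.numeric(col("beta")) else log(as.numeric(col("or_col")))
  df <- data.frame(
    snp_id = as.character(col("snp_id", NA_character_)),
    chrom = as.character(col("chrom", NA_character_)),
    pos = as.integer(col("pos")),
    effect_allele = toupper(as.character(col("effect_allele", NA_character_))),
    other_allele = toupper(as.character(col("other_allele", NA_character_))),
    eaf = as.numeric(col("eaf")),
    beta = beta,
    se = as.numeric(col("se")),
    p = as.numeric(col("p")),
    n = as.numeric(col("n")),
    stringsAsFactors = FALSE
  )
  validate_sumstats(df)
}

#' Write a summary-statistics table as tab-delimited text
#'
#' Lossless round trip with [read_sumstats()] for all fields.
#'
#' @param table A `sumstats` object.
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @export
write_sumstats <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

new_ldscores <- function(df, m_total) {
  stopifnot(is.data.frame(df), all(c("snp_id", "ldscore") %in% names(df)))
  if (any(!is.finite(df$ldscore)) || any(df$ldscore < 0)) {
    stop("ldscore values must be finite and >= 0")
  }
  class(df) <- c("ldscores", "data.frame")
  attr(df, "m_total") <- as.numeric(m_total)
  df
}

#' Read per-SNP LD scores
#'
#' Accepts the internal dialect (`snp_id`, `ldscore`) and LDSC-style column
#' names (`SNP`, `L2`). The total SNP count M used by LD score regression is
#' read from a leading `# m_total <count>` comment line when present, otherwise
#' taken from `m_total`, defaulting to the number of rows.
#'
#' @param path Path to a delimited text file.
#' @param m_total Optional override for the total SNP count M.
#' @return An `ldscores` data.frame with attribute `m_total`.
#' @export
read_ldscores <- function(path, m_total = NULL) {
  first <- .read_first_line(path)
  file_m <- NULL
  if (startsWith(first, "#")) {
    toks <- strsplit(trimws(sub("^#+", "", first)), "\\s+")[[1]]
    if (length(toks) >= 2 && toks[1] == "m_total") file_m <- as.numeric(toks[2])
  }
  raw <- .fread_auto(path, skip = if (is.null(file_m)) 0L else 1L)
  hdr <- tolower(names(raw))
  si <- match(c("snp_id", "snp", "rsid"), hdr); si <- si[!is.na(si)][1]
  li <- match(c("ldscore", "l2", "ld"), hdr); li <- li[!is.na(li)][1]
  if (is.na(si) || is.na(li)) stop("read_ldscores: need SNP id and LD score columns (snp_id/SNP, ldscore/L2)")
  df <- data.frame(snp_id = as.character(raw[[si]]), ldscore = as.numeric(raw[[li]]),
                   stringsAsFactors = FALSE)
  m <- if (!is.null(m_total)) m_total else if (!is.null(file_m)) file_m else nrow(df)
  new_ldscores(df, m)
}

#' Write per-SNP LD scores
#'
#' Writes a `# m_total <count>` header line followed by a tab-delimited table.
#'
#' @param ld An `ldscores` object.
#' @param path Output path.
#' @export
write_ldscores <- function(ld, path) {
  con <- file(path, "w")
  writeLines(sprintf("# m_total %s", format(attr(ld, "m_total"), scientific = FALSE)), con)
  close(con)
  data.table::fwrite(as.data.frame(ld), path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

new_ld_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("snp_a", "snp_b", "r2") %in% names(df)))
  class(df) <- c("ld_table", "data.frame")
  df
}

#' Read a pairwise LD (r-squared) table
#'
#' Long format with columns `snp_a`, `snp_b`, `r2`. Validation requires all r2
#' in [0, 1], unit self-pairs, and symmetry: if both orientations of a pair are
#' present they must agree.
#'
#' @param path Path to a delimited text file.
#' @return An `ld_table` data.frame.
#' @export
read_ld_matrix <- function(path) {
  raw <- .fread_auto(path)
  names(raw) <- tolower(names(raw))
  if (!all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    stop("read_ld_matrix: need columns snp_a, snp_b, r2")
  }
  df <- data.frame(snp_a = as.character(raw$snp_a), snp_b = as.character(raw$snp_b),
                   r2 = as.numeric(raw$r2), stringsAsFactors = FALSE)
  validate_ld_table(df)
}

validate_ld_table <- function(df) {
  if (any(!is.finite(df$r2)) || any(df$r2 < 0) || any(df$r2 > 1)) {
    stop("ld table: r2 values must lie in [0, 1]")
  }
  diag_rows <- df$snp_a == df$snp_b
  if (any(df$r2[diag_rows] != 1)) stop("ld table: self-pairs must have r2 = 1")
  key_fwd <- paste(df$snp_a, df$snp_b, sep = "\r")
  key_rev <- paste(df$snp_b, df$snp_a, sep = "\r")
  hit <- match(key_rev, key_fwd)
  both <- !is.na(hit)
  if (any(both) && any(abs(df$r2[both] - df$r2[hit[both]]) > 1e-9)) {
    stop("ld table: asymmetric r2 entries")
  }
  new_ld_table(df)
}

#' Write a pairwise LD table
#' @param ld An `ld_table` object.
#' @param path Output path.
#' @export
write_ld_matrix <- function(ld, path) {
  data.table::fwrite(as.data.frame(ld), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a confounder SNP blocklist
#'
#' A local stand-in for database lookups of SNP-trait associations with known
#' disease risk factors (e.g. age, smoking): columns `snp_id`, `trait_label`.
#'
#' @param path Path to a delimited text file.
#' @return A `blocklist` data.frame.
#' @export
read_blocklist <- function(path) {
  raw <- .fread_auto(path)
  names(raw) <- tolower(names(raw))
  if (!all(c("snp_id", "trait_label") %in% names(raw))) {
    stop("read_blocklist: need columns snp_id, trait_label")
  }
  df <- data.frame(snp_id = as.character(raw$snp_id),
                   trait_label = as.character(raw$trait_label),
                   stringsAsFactors = FALSE)
  class(df) <- c("blocklist", "data.frame")
  df
}

#' Write a confounder SNP blocklist
#' @param bl A `blocklist` data.frame.
#' @param path Output path.
#' @export
write_blocklist <- function(bl, path) {
  data.table::fwrite(as.data.frame(bl), path, sep = "\t", quote = FALSE)
  invisible(path)
}
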