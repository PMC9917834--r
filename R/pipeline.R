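#' Configuration for the two-stage screen
#'
#' One object carries every threshold of the pipeline: instrument selection
#' p-value, clumping parameters, outcome-exclusion p-value, the shared
#' significance level, bootstrap/simulation sizes, seed, and the refinement
#' round cap.
#'
#' @param exposure_p Exposure instrument p-value threshold (default 5e-6).
#' @param outcome_p Outcome-association exclusion threshold (default 5e-6).
#' @param clump_r2 Clumping r-squared threshold (default 0.001).
#' @param clump_kb Clumping distance in kb (default 10,000).
#' @param alpha Significance level used throughout (default 0.05).
#' @param rg_p Selection threshold on the genetic-correlation p-value
#'   (default 0.05, nominal, no multiple-testing correction; set
#'   `rg_p_adjust` to a [stats::p.adjust()] method to enable one).
#' @param rg_p_adjust Multiple-testing correction method (default "none").
#' @param n_boot Bootstrap draws for median/mode SEs.
#' @param n_sim MR-PRESSO simulated null datasets.
#' @param n_blocks LDSC jackknife blocks.
#' @param max_rounds Refinement round cap (default 5).
#' @param phi Mode-estimator bandwidth multiplier.
#' @param seed Integer seed driving all stochastic components.
#' @return An `mr_config` list.
#' @export
mr_config <- function(exposure_p = 5e-6, outcome_p = 5e-6,
                      clump_r2 = 0.001, clump_kb = 10000,
                      alpha = 0.05, rg_p = 0.05, rg_p_adjust = "none",
                      n_boot = 1000, n_sim = 1000, n_blocks = 200,
                      max_rounds = 5, phi = 1, seed = 1) {
  structure(list(exposure_p = exposure_p, outcome_p = outcome_p,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 alpha = alpha, rg_p = rg_p, rg_p_adjust = rg_p_adjust,
                 n_boot = n_boot, n_sim = n_sim, n_blocks = n_blocks,
                 max_rounds = max_rounds, phi = phi, seed = as.integer(seed)),
            class = "mr_config")
}

.verdict <- function(ivw, alpha) {
  if (is.na(ivw$p)) return("not_evaluable")
  if (ivw$p < alpha && ivw$beta > 0) "causal_positive"
  else if (ivw$p < alpha && ivw$beta < 0) "causal_negative"
  else "no_causal"
}

#' Iterative instrument-refinement engine
#'
#' Runs rounds of the full estimator + sensitivity battery on a harmonized
#' instrument set and removes flagged instruments between rounds:
#' if the MR-PRESSO global test rejects at `alpha`, the Bonferroni-significant
#' outliers are removed (or, when none exist, the nominally-significant
#' potential outliers); otherwise, if leave-one-out flags influential
#' instruments, those are removed; otherwise the analysis is clean and the
#' engine stops. The verdict comes solely from the final round's
#' random-effects IVW: direction of the effect with p below `alpha`.
#'
#' @param ivs A `harmonized_ivs` table with at least 3 rows, or NULL if
#'   `exposure`/`outcome` tables are given.
#' @param exposure,outcome,ld,blocklist Raw inputs for [build_instruments()]
#'   (used only when `ivs` is NULL).
#' @param config An [mr_config()].
#' @return A `refinement_log`: `rounds` (each with `round_index`, `ivs_used`,
#'   `removed_before_round`, `removal_reason`, `mr_results`, `sensitivity`),
#'   `final_round_index`, `verdict` (`causal_positive` / `causal_negative` /
#'   `no_causal` / `not_evaluable`), `stop_reason` (`clean` / `max_rounds` /
#'   `too_few_instruments`).
#' @export
run_refinement <- function(ivs = NULL, exposure = NULL, outcome = NULL,
                           ld = NULL, blocklist = NULL, config = mr_config()) {
  if (is.null(ivs)) {
    ivs <- build_instruments(exposure, outcome, ld, blocklist,
                             exposure_p = config$exposure_p, outcome_p = config$outcome_p,
                             clump_r2 = config$clump_r2, clump_kb = config$clump_kb)
  }
  if (nrow(ivs) < 3) {
    stop(sprintf("run_refinement: harmonization yielded %d instrument(s); need at least 3",
                 nrow(ivs)))
  }
  rounds <- list()
  removed_before <- character(0)
  removal_reason <- NA_character_
  stop_reason <- "max_rounds"
  verdict <- NA_character_
  cur <- ivs
  for (r in seq_len(config$max_rounds)) {
    res <- mr_all(cur, phi = config$phi, n_boot = config$n_boot,
                  seed = config$seed + 13L * r)
    sens <- sensitivity_report(cur, n_sim = config$n_sim,
                               seed = config$seed + 13L * r + 7L,
                               alpha = config$alpha)
    rounds[[r]] <- list(round_index = r, ivs_used = cur$snp_id,
                        removed_before_round = removed_before,
                        removal_reason = removal_reason,
                        mr_results = res, sensitivity = sens)
    to_remove <- character(0)
    reason <- NA_character_
    if (sens$presso$available && !is.na(sens$presso$global_p) &&
        sens$presso$global_p < config$alpha) {
      if (length(sens$presso$outliers)) {
        to_remove <- sens$presso$outliers; reason <- "presso_outlier"
      } else if (length(sens$presso$potential_outliers)) {
        to_remove <- sens$presso$potential_outliers; reason <- "presso_potential_outlier"
      }
    }
    if (!length(to_remove) && !is.null(sens$loo) && length(sens$loo$influential_snps)) {
      to_remove <- sens$loo$influential_snps; reason <- "loo_influential"
    }
    if (!length(to_remove)) { stop_reason <- "clean"; break }
    if (nrow(cur) - length(to_remove) < 3) {
      stop_reason <- "too_few_instruments"
      verdict <- "not_evaluable"
      break
    }
    if (r == config$max_rounds) { stop_reason <- "max_rounds"; break }
    cur <- cur[!(cur$snp_id %in% to_remove), , drop = FALSE]
    removed_before <- to_remove
    removal_reason <- reason
  }
  final <- length(rounds)
  if (is.na(verdict)) {
    verdict <- .verdict(rounds[[final]]$mr_results$ivw_re, config$alpha)
  }
  structure(list(rounds = rounds, final_round_index = final,
                 verdict = verdict, stop_reason = stop_reason),
            class = "refinement_log")
}

#' @export
print.refinement_log <- function(x, ...) {
  cat(sprintf("Refinement: %d round(s), stop = %s, verdict = %s\n",
              x$final_round_index, x$stop_reason, x$verdict))
  for (r in x$rounds) {
    ivw <- r$mr_results$ivw_re
    rem <- if (length(r$removed_before_round)) {
      sprintf(" [removed before: %s (%s)]",
              paste(r$removed_before_round, collapse = ", "), r$removal_reason)
    } else ""
    cat(sprintf("  round %d: k = %d, IVW OR = %.3f, p = %.3g%s\n",
                r$round_index, length(r$ivs_used), ivw$or_value, ivw$p, rem))
  }
  invisible(x)
}

#' Two-stage metabolome-wide screen
#'
#' Stage one fits the bivariate genetic correlation between each exposure and
#' the outcome by LD score regression; exposures with a correlation p-value
#' below `config$rg_p` (after the configured adjustment, default none) are
#' selected. Stage two runs the instrument screen plus the iterative MR
#' refinement on every selected exposure. Per-exposure failures are recorded
#' in the report, not fatal to the screen.
#'
#' @param outcome A `sumstats` table for the disease trait.
#' @param exposures Named list of `sumstats` tables (one per metabolite).
#' @param ld An `ldscores` table.
#' @param ld_pairs LD information for clumping (`ld_table` / `ld_blocks` /
#'   NULL).
#' @param blocklist Optional confounder `blocklist`.
#' @param config An [mr_config()].
#' @return A `screen_report`: `table` (label, rg, rg_se, rg p, selected,
#'   verdict, error) and `refinements` (named list of `refinement_log`s for
#'   the selected exposures).
#' @export
run_screen <- function(outcome, exposures, ld, ld_pairs = NULL, blocklist = NULL,
                       config = mr_config()) {
  labels <- names(exposures) %||% sprintf("exposure_%d", seq_along(exposures))
  refinements <- list()
  if (!length(exposures)) {
    tab <- data.frame(label = character(0), rg = numeric(0), rg_se = numeric(0),
                      rg_p = numeric(0), selected = logical(0),
                      verdict = character(0), error = character(0),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, refinements = refinements, config = config),
                     class = "screen_report"))
  }
  rows <- list()
  rg_fits <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    rows[[i]] <- data.frame(label = labels[i], rg = NA_real_, rg_se = NA_real_,
                            rg_p = NA_real_, selected = FALSE,
                            verdict = NA_character_, error = NA_character_,
                            stringsAsFactors = FALSE)
    rg_fits[[i]] <- tryCatch(
      fit_rg(exposures[[i]], outcome, ld, n_blocks = config$n_blocks),
      error = function(e) e
    )
    if (inherits(rg_fits[[i]], "error")) {
      rows[[i]]$error <- conditionMessage(rg_fits[[i]])
    } else {
      rows[[i]]$rg <- rg_fits[[i]]$rg
      rows[[i]]$rg_se <- rg_fits[[i]]$rg_se
      rows[[i]]$rg_p <- rg_fits[[i]]$p
    }
  }
  tab <- do.call(rbind, rows)
  padj <- stats::p.adjust(tab$rg_p, method = config$rg_p_adjust)
  tab$selected <- !is.na(padj) & padj < config$rg_p
  for (i in which(tab$selected)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    ref <- tryCatch(
      run_refinement(exposure = exposures[[i]], outcome = outcome, ld = ld_pairs,
                     blocklist = blocklist, config = cfg_i),
      error = function(e) e
    )
    if (inherits(ref, "error")) {
      tab$error[i] <- conditionMessage(ref)
    } else {
      refinements[[tab$label[i]]] <- ref
      tab$verdict[i] <- ref$verdict
    }
  }
  structure(list(table = tab, refinements = refinements, config = config),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  n_sel <- sum(x$table$selected, na.rm = TRUE)
  cat(sprintf("Screen of %d exposure(s): %d selected at rg p < %g\n",
              nrow(x$table), n_sel, x$config$rg_p))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Genetic-correlation report table (one row per exposure)
#'
#' @param screen A `screen_report`.
#' @return data.frame with label, correlation coefficient and p-value.
#' @export
rg_table <- function(screen) {
  data.frame(label = screen$table$label,
             correlation_coefficient = screen$table$rg,
             p_value = screen$table$rg_p, stringsAsFactors = FALSE)
}
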