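#' Pipeline configuration
#'
#' Bundles every tunable threshold of the workflow. Defaults are the study
#' conditions: Ct censoring at 35 cycles, DEG gate at a 2-fold regulation with
#' t-test p < 0.05, pathway-analysis input filter at +/-1.5 fold regulation
#' and p <= 0.05, overlap-p grade thresholds 0.0005 / 0.005 / 0.05, protein
#' grade bands at 150% and 200% of solvent control, viability rule > 80%.
#'
#' @param ct_cutoff Ct censoring cutoff in cycles.
#' @param fc_threshold DEG fold-regulation threshold (inclusive).
#' @param alpha significance level for DEG calling (strict `<`) and the
#'   pathway-analysis input filter (`<=`).
#' @param fr_cutoff fold-regulation cutoff for the pathway-analysis input.
#' @param ipa_p_grades increasing overlap-p thresholds for
#'   very_strong / strong / medium transcript grades.
#' @param protein_grade_bounds increasing percent-of-control bounds delimiting
#'   the medium band `(150, 200]` and the strong band `> 200`.
#' @param viability_threshold percent viability a concentration must strictly
#'   exceed to count as non-cytotoxic.
#' @param qc_tolerance maximal fold ratio between array and single-assay
#'   qPCR fold changes accepted by [qc_range_check()].
#' @param n_boot bootstrap resamples for protein-panel significance.
#' @param rng_seed integer seed from which every stochastic step derives.
#' @param collapse_rule how a category inherits its annotations' overlap p:
#'   `"min_p"` keeps the most significant annotation (default), `"max_p"` is
#'   the literal weakest-annotation reading, kept for sensitivity analysis.
#' @param score_unmapped_effects if TRUE, in vivo effects without any mapped
#'   in vitro predictor are kept in the concordance denominator as automatic
#'   misses (sensitivity analysis); default drops them.
#' @return object of class `tox_config` (a validated list).
#' @examples
#' cfg <- tox_config(alpha = 0.01)
#' cfg$alpha
#' @export
tox_config <- function(ct_cutoff = 35,
                       fc_threshold = 2,
                       alpha = 0.05,
                       fr_cutoff = 1.5,
                       ipa_p_grades = c(0.0005, 0.005, 0.05),
                       protein_grade_bounds = c(150, 200),
                       viability_threshold = 80,
                       qc_tolerance = 3,
                       n_boot = 10000,
                       rng_seed = 1L,
                       collapse_rule = c("min_p", "max_p"),
                       score_unmapped_effects = FALSE) {
  collapse_rule <- match.arg(collapse_rule)
  num_pos <- c(ct_cutoff = ct_cutoff, fc_threshold = fc_threshold,
               alpha = alpha, fr_cutoff = fr_cutoff,
               viability_threshold = viability_threshold,
               qc_tolerance = qc_tolerance, n_boot = n_boot)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad)) {
    tc_stop(sprintf("configuration thresholds must be strictly positive: %s",
                    paste(bad, collapse = ", ")), "toxconcord_config_error")
  }
  if (length(ipa_p_grades) != 3 || any(diff(ipa_p_grades) <= 0) ||
      any(ipa_p_grades <= 0) || any(ipa_p_grades > 1)) {
    tc_stop("ipa_p_grades must be three strictly increasing probabilities",
            "toxconcord_config_error")
  }
  if (length(protein_grade_bounds) != 2 || diff(protein_grade_bounds) <= 0 ||
      any(protein_grade_bounds <= 0)) {
    tc_stop("protein_grade_bounds must be two strictly increasing percentages",
            "toxconcord_config_error")
  }
  structure(list(
    ct_cutoff = ct_cutoff, fc_threshold = fc_threshold, alpha = alpha,
    fr_cutoff = fr_cutoff, ipa_p_grades = ipa_p_grades,
    protein_grade_bounds = protein_grade_bounds,
    viability_threshold = viability_threshold, qc_tolerance = qc_tolerance,
    n_boot = as.integer(n_boot), rng_seed = as.integer(rng_seed),
    collapse_rule = collapse_rule,
    score_unmapped_effects = isTRUE(score_unmapped_effects)
  ), class = "tox_config")
}

#' @export
print.tox_config <- function(x, ...) {
  cat("<tox_config>\n")
  cat(sprintf("  Ct cutoff: %g cycles | DEG gate: |FR| >= %g & p < %g\n",
              x$ct_cutoff, x$fc_threshold, x$alpha))
  cat(sprintf("  IPA input: |FR| >= %g & p <= %g | grade p: <=%g/<=%g/<=%g\n",
              x$fr_cutoff, x$alpha,
              x$ipa_p_grades[1], x$ipa_p_grades[2], x$ipa_p_grades[3]))
  cat(sprintf("  Protein bands: (%g, %g] medium, > %g strong\n",
              x$protein_grade_bounds[1], x$protein_grade_bounds[2],
              x$protein_grade_bounds[2]))
  cat(sprintf("  Viability: > %g%% | QC tolerance: %g-fold | bootstrap: %d | seed: %d\n",
              x$viability_threshold, x$qc_tolerance, x$n_boot, x$rng_seed))
  invisible(x)
}
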