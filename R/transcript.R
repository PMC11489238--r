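# Transcript evidence: filtering of pathway-analysis inputs and annotation
# exports, collapse of annotations to categories, p-value grading.

#' Filter an expression table for pathway-analysis upload
#'
#' Retains genes with `|fold_regulation| >= fr_cutoff` and `p <= alpha` —
#' the input filter applied before a disease-or-function core analysis.
#'
#' @param expr `expression_table`.
#' @param fr_cutoff fold-regulation cutoff (inclusive).
#' @param alpha p-value cutoff (inclusive).
#' @return the retained rows, same class.
#' @export
filter_ipa_input <- function(expr, fr_cutoff = 1.5, alpha = 0.05) {
  require_columns(expr, c("fold_regulation", "p_value"), "expression table")
  keep <- abs(expr$fold_regulation) >= fr_cutoff &
    !is.na(expr$p_value) & expr$p_value <= alpha
  expr[keep, , drop = FALSE]
}

#' Keep only liver- and kidney-relevant annotation categories
#'
#' Predicted effects on organs other than the liver and kidneys (heart,
#' lung, ...) are discarded by matching the category against a whitelist of
#' organ-relevant category names.
#'
#' @param records `annotation_table`.
#' @param whitelist character vector of category names to keep; defaults to
#'   the packaged [category_whitelist()].
#' @param logger optional log collector.
#' @return the retained rows.
#' @export
filter_organ_categories <- function(records, whitelist = category_whitelist(),
                                    logger = NULL) {
  require_columns(records, "category", "annotation table")
  keep <- records$category %in% whitelist
  if (!is.null(logger) && any(!keep)) {
    dropped <- unique(records$category[!keep])
    logger$log("filter_organ_categories: dropped %d record(s) [reason=off_organ]: %s",
               sum(!keep), paste(dropped, collapse = ", "))
  }
  records[keep, , drop = FALSE]
}

#' Collapse annotations to one row per category
#'
#' Each (substance, input scope, category) keeps the overlap p-value of its
#' most significant annotation (`"min_p"`, the default); the literal
#' weakest-annotation reading (`"max_p"`) is available for sensitivity
#' analysis.
#'
#' @param records `annotation_table`.
#' @param rule `"min_p"` or `"max_p"`.
#' @return data.frame with `substance`, `input_scope`, `category`, `best_p`.
#' @export
collapse_to_category <- function(records, rule = c("min_p", "max_p")) {
  rule <- match.arg(rule)
  require_columns(records, c("substance", "input_scope", "category",
                             "p_overlap"), "annotation table")
  if (nrow(records) == 0) {
    return(data.frame(substance = character(0), input_scope = character(0),
                      category = character(0), best_p = numeric(0)))
  }
  f <- if (rule == "min_p") min else max
  out <- aggregate(p_overlap ~ substance + input_scope + category, records, f)
  names(out)[names(out) == "p_overlap"] <- "best_p"
  out[order(out$substance, out$input_scope, out$category), , drop = FALSE]
}

#' Grade a category from its best overlap p-value
#'
#' very_strong iff `p <= 0.0005`; else strong iff `p <= 0.005`; else medium
#' iff `p <= 0.05`; else none. Antitone in p.
#'
#' @param best_p probability vector.
#' @param thresholds increasing p thresholds for very_strong/strong/medium.
#' @return ordered factor of grades.
#' @examples
#' grade_category(c(4e-4, 0.02, 0.2))
#' @export
grade_category <- function(best_p, thresholds = c(0.0005, 0.005, 0.05)) {
  if (any(is.na(best_p) | best_p <= 0 | best_p > 1)) {
    tc_stop("best_p must lie in (0, 1]", "toxconcord_domain_error")
  }
  g <- ifelse(best_p <= thresholds[1], "very_strong",
       ifelse(best_p <= thresholds[2], "strong",
       ifelse(best_p <= thresholds[3], "medium", "none")))
  evidence_grade(g)
}

#' Graded category evidence from annotation exports
#'
#' Organ filtering, collapse to categories and p-value grading in one step.
#'
#' @param records `annotation_table` (see [read_annotation_export()]).
#' @param config [tox_config()]; supplies grade thresholds and collapse rule.
#' @param whitelist category whitelist for [filter_organ_categories()].
#' @param logger optional log collector.
#' @return `category_evidence` data.frame: `substance`, `input_scope`,
#'   `category`, `best_p`, `grade`.
#' @export
category_evidence <- function(records, config = tox_config(),
                              whitelist = category_whitelist(),
                              logger = NULL) {
  records <- as_annotation_table(as.data.frame(records))
  records <- filter_organ_categories(records, whitelist, logger)
  out <- collapse_to_category(records, config$collapse_rule)
  out$grade <- as.character(grade_category(out$best_p, config$ipa_p_grades))
  rownames(out) <- NULL
  class(out) <- c("category_evidence", "data.frame")
  out
}

#' @export
print.category_evidence <- function(x, ...) {
  cat(sprintf("<category_evidence> %d category calls across %d substance(s)\n",
              nrow(x), length(unique(x$substance))))
  NextMethod()
}
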