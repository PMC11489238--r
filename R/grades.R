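#' Ordinal evidence grades
#'
#' In vitro evidence is graded on the ordinal scale
#' none < medium < strong < very_strong. Grades are represented as ordered
#' factors so that threshold filters ("at least strong") are plain
#' comparisons.
#'
#' @param x character, factor or grade vector; `""` and `NA` map to `"none"`.
#' @return An ordered factor with levels `none < medium < strong < very_strong`.
#' @examples
#' evidence_grade(c("strong", "none")) >= "medium"
#' @export
evidence_grade <- function(x) {
  lev <- grade_levels()
  x <- tolower(as.character(x))
  x[is.na(x) | x == ""] <- "none"
  bad <- setdiff(unique(x), lev)
  if (length(bad)) {
    tc_stop(sprintf("unknown evidence grade(s): %s (valid: %s)",
                    paste(bad, collapse = ", "), paste(lev, collapse = " < ")),
            "toxconcord_vocabulary_error")
  }
  factor(x, levels = lev, ordered = TRUE)
}

#' @rdname evidence_grade
#' @export
grade_levels <- function() c("none", "medium", "strong", "very_strong")

#' Parallel maximum of evidence grades
#'
#' @param ... grade vectors (anything [evidence_grade()] accepts), recycled.
#' @return ordered factor of element-wise maxima.
#' @export
grade_max <- function(...) {
  gs <- lapply(list(...), evidence_grade)
  idx <- do.call(pmax, lapply(gs, as.integer))
  factor(grade_levels()[idx], levels = grade_levels(), ordered = TRUE)
}
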