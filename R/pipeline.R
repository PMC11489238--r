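# End-to-end orchestration: chain quantification, evidence grading, mapping
# and concordance, write machine- and human-readable outputs, and log every
# threshold applied.

stage <- function(name, expr) {
  tryCatch(expr, toxconcord_error = function(e) {
    tc_stop(sprintf("stage %s: %s", name, conditionMessage(e)),
            class(e)[1])
  }, error = function(e) {
    tc_stop(sprintf("stage %s: %s", name, conditionMessage(e)),
            "toxconcord_stage_error")
  })
}

load_or <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full concordance pipeline
#'
#' Chains every stage on the supplied inputs: optional delta-delta-Ct
#' quantification of Ct tables (plus DEG summary when a pathway catalog is
#' given), protein-marker grading with bootstrap significance, transcript
#' category grading, and the scope x threshold concordance sweep against
#' the in vivo observation registry. The run is a pure function of
#' (inputs, config): re-running writes byte-identical outputs; only the
#' bootstrap p-values consume randomness, and they derive from
#' `config$rng_seed`.
#'
#' @param inputs list with any of: `protein_panel`, `annotations`,
#'   `in_vivo`, `ct` (one `ct_table` or a list of them), `catalog`,
#'   `protein_map`, `category_map` — each an object or a CSV path.
#'   Ontologies default to the packaged tables. A [simulate_study()] bundle
#'   can be passed directly.
#' @param config [tox_config()].
#' @param out_dir directory for report files (created); `NULL` skips writing.
#' @param cell_line_organs named vector assigning protein cell lines to
#'   organs, passed to [threshold_sweep()].
#' @return `tox_pipeline_result`: list with `sweep`, `marker_evidence`,
#'   `category_evidence`, `expression` (named list), `deg_summary`, `log`.
#' @export
run_pipeline <- function(inputs, config = tox_config(), out_dir = NULL,
                         cell_line_organs = c(HepaRG = "liver",
                                              RPTEC = "kidney")) {
  logger <- tc_logger()
  logger$log("config: ct_cutoff=%g fc_threshold=%g alpha=%g fr_cutoff=%g",
             config$ct_cutoff, config$fc_threshold, config$alpha,
             config$fr_cutoff)
  logger$log("config: ipa_p_grades=%s protein_grade_bounds=%s seed=%d",
             paste(config$ipa_p_grades, collapse = "/"),
             paste(config$protein_grade_bounds, collapse = "/"),
             config$rng_seed)

  in_vivo <- stage("load_in_vivo",
                   load_or(inputs$in_vivo, function(p)
                     load_ontology("in_vivo", p)) %||% load_ontology("in_vivo"))
  protein_map <- stage("load_protein_map",
                       load_or(inputs$protein_map, function(p)
                         load_ontology("protein_map", p)) %||%
                         load_ontology("protein_map"))
  category_map <- stage("load_category_map",
                        load_or(inputs$category_map, function(p)
                          load_ontology("category_map", p)) %||%
                          load_ontology("category_map"))

  expression <- NULL
  deg_summary <- NULL
  if (!is.null(inputs$ct)) {
    cts <- inputs$ct
    if (inherits(cts, "data.frame") || is.character(cts)) cts <- list(cts)
    expression <- stage("quantify", lapply(cts, function(x) {
      quantify_expression(load_or(x, read_ct_table), config, logger = logger)
    }))
    if (!is.null(inputs$catalog)) {
      catalog <- stage("load_catalog",
                       load_or(inputs$catalog, read_pathway_catalog))
      deg_summary <- stage("deg_summary", lapply(expression, function(e) {
        deg <- call_deg(e, config$fc_threshold, config$alpha)
        logger$log("call_deg: |FR|>=%g & p<%g -> %d DEG",
                   config$fc_threshold, config$alpha, length(deg))
        pct_deg(deg, catalog)
      }))
    }
  }

  protein_ev <- NULL
  if (!is.null(inputs$protein_panel)) {
    protein_ev <- stage("protein_evidence", {
      panel <- load_or(inputs$protein_panel, read_protein_panel)
      logger$log("grade_protein: bands (%g,%g] / >%g; bootstrap n=%d",
                 config$protein_grade_bounds[1], config$protein_grade_bounds[2],
                 config$protein_grade_bounds[2], config$n_boot)
      marker_evidence(panel, config)
    })
  }

  transcript_ev <- NULL
  if (!is.null(inputs$annotations)) {
    transcript_ev <- stage("transcript_evidence", {
      ann <- load_or(inputs$annotations, read_annotation_export)
      logger$log("grade_category: p thresholds %s; collapse=%s",
                 paste(config$ipa_p_grades, collapse = "/"),
                 config$collapse_rule)
      category_evidence(ann, config, logger = logger)
    })
  }

  if (is.null(protein_ev) && is.null(transcript_ev)) {
    tc_stop("stage sweep: no evidence inputs (protein_panel or annotations)",
            "toxconcord_input_error")
  }
  sweep <- stage("concordance", threshold_sweep(
    protein_ev, transcript_ev, in_vivo, protein_map, category_map, config,
    cell_line_organs))

  result <- structure(list(
    sweep = sweep, marker_evidence = protein_ev,
    category_evidence = transcript_ev, expression = expression,
    deg_summary = deg_summary, log = logger$lines()),
    class = "tox_pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  if (!is.null(result$expression)) {
    for (nm in names(result$expression) %||% seq_along(result$expression)) {
      write.csv(as.data.frame(result$expression[[nm]]),
                out(sprintf("expression_%s.csv", nm)), row.names = FALSE)
    }
  }
  if (!is.null(result$deg_summary)) {
    for (nm in names(result$deg_summary) %||% seq_along(result$deg_summary)) {
      write.csv(as.data.frame(result$deg_summary[[nm]]),
                out(sprintf("deg_summary_%s.csv", nm)), row.names = FALSE)
    }
  }
  if (!is.null(result$marker_evidence)) {
    write.csv(as.data.frame(result$marker_evidence),
              out("marker_evidence.csv"), row.names = FALSE)
  }
  if (!is.null(result$category_evidence)) {
    write.csv(as.data.frame(result$category_evidence),
              out("category_evidence.csv"), row.names = FALSE)
  }
  write.csv(as.data.frame(result$sweep), out("concordance_sweep.csv"),
            row.names = FALSE)
  audits <- attr(result$sweep, "audits")
  audit <- do.call(rbind, lapply(names(audits), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (nrow(audits[[k]]) == 0) return(NULL)
    cbind(scope = parts[1], threshold = parts[2], audits[[k]])
  }))
  if (is.null(audit)) {
    audit <- data.frame(scope = character(0), threshold = character(0))
  }
  write.csv(audit, out("concordance_audit.csv"), row.names = FALSE)
  report <- list(
    concordance = as.data.frame(result$sweep),
    generated_by = "toxconcord")
  jsonlite::write_json(report, out("report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(result$log, out("pipeline_log.txt"))
  invisible(out_dir)
}

#' @export
print.tox_pipeline_result <- function(x, ...) {
  cat("<tox_pipeline_result>\n")
  if (!is.null(x$marker_evidence)) {
    cat(sprintf("  protein evidence: %d calls\n", nrow(x$marker_evidence)))
  }
  if (!is.null(x$category_evidence)) {
    cat(sprintf("  transcript evidence: %d calls\n", nrow(x$category_evidence)))
  }
  print(x$sweep)
  invisible(x)
}
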