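# The concordance engine: graded in vitro endpoints are mapped through the
# curated effect ontologies onto (substance, organ, effect) triples and
# scored against the in vivo observation registry.

evidence_endpoints <- function(evidence) {
  df <- as.data.frame(evidence)
  col <- intersect(c("endpoint", "cellular_function", "category"), names(df))
  if (length(col) == 0) {
    tc_stop("evidence needs an endpoint, cellular_function or category column",
            "toxconcord_schema_error")
  }
  data.frame(substance = df$substance, endpoint = df[[col[1]]],
             grade = as.character(evidence_grade(df$grade)),
             stringsAsFactors = FALSE)
}

#' Map graded evidence onto predicted in vivo effects
#'
#' Every mapping endpoint whose grade reaches the threshold contributes all
#' of its mapped effect categories for the requested organ(s). A
#' combination endpoint (several member categories) fires only when *all*
#' members reach the threshold, and contributes the weakest member grade.
#' Multiple endpoints predicting the same effect are OR-combined: the
#' prediction keeps the strongest supporting grade.
#'
#' @param evidence `marker_evidence` or `category_evidence` (any table with
#'   `substance`, `grade` and an endpoint column).
#' @param mapping `effect_mapping` from [load_ontology()].
#' @param threshold minimal grade (`"medium"`, `"strong"`, `"very_strong"`).
#' @param organs organs the evidence may predict for; defaults to both.
#' @return `prediction_set` data.frame: `substance`, `organ`, `effect`,
#'   `grade` (best supporting), `endpoints` (contributors, `"; "`-separated).
#' @examples
#' ev <- data.frame(substance = "S", cellular_function = "Translation",
#'                  grade = "strong")
#' map_predictions(ev, load_ontology("protein_map"), "medium", "liver")
#' @export
map_predictions <- function(evidence, mapping,
                            threshold = c("medium", "strong", "very_strong"),
                            organs = c("liver", "kidney")) {
  if (is.character(threshold)) threshold <- match.arg(threshold)
  threshold <- evidence_grade(as.character(threshold))
  stopifnot(inherits(mapping, "effect_mapping"))
  ev <- evidence_endpoints(evidence)
  ev$grade <- evidence_grade(ev$grade)

  map <- mapping[!is.na(mapping$effect) & mapping$organ %in% organs, ,
                 drop = FALSE]
  rows <- vector("list", 0L)
  thr <- as.integer(threshold)
  for (s in unique(ev$substance)) {
    evs <- ev[ev$substance == s, ]
    # best grade (integer code) per evidence endpoint for this substance
    best <- tapply(as.integer(evs$grade), evs$endpoint, max)
    for (i in seq_len(nrow(map))) {
      members <- map$members[[i]]
      g <- best[members]
      if (any(is.na(g)) || any(g < thr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        substance = s, organ = map$organ[i], effect = map$effect[i],
        grade = grade_levels()[min(g)], endpoints = map$endpoint[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(substance = character(0), organ = character(0),
               effect = character(0), grade = character(0),
               endpoints = character(0), stringsAsFactors = FALSE)
  out <- dedupe_predictions(out)
  class(out) <- c("prediction_set", "data.frame")
  out
}

dedupe_predictions <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$substance, df$organ, df$effect, sep = "\r")
  rows <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub$grade <- as.character(max(evidence_grade(sub$grade)))
    sub$endpoints <- paste(sort(unique(unlist(
      strsplit(sub$endpoints, "; ", fixed = TRUE)))), collapse = "; ")
    sub[1, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$substance, out$organ, out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' OR-combine prediction sets
#'
#' Union per (substance, organ, effect); a triple predicted by any
#' contributing set is predicted by the combination, with the strongest
#' supporting grade. Idempotent, commutative, associative.
#'
#' @param ... `prediction_set` objects (or a single list of them).
#' @return combined `prediction_set`.
#' @export
combine_scopes <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "data.frame")) sets <- sets[[1]]
  out <- dedupe_predictions(do.call(rbind, lapply(sets, as.data.frame)))
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Reachable in vivo effect targets of a mapping
#'
#' The distinct (organ, effect) pairs at least one endpoint of the mapping
#' can predict — the evaluation universe a scope is scored on.
#'
#' @param mapping `effect_mapping`.
#' @param organs organs to keep.
#' @return data.frame with columns `organ`, `effect`.
#' @export
mapping_targets <- function(mapping, organs = c("liver", "kidney")) {
  t <- unique(as.data.frame(mapping)[!is.na(mapping$effect) &
                                       mapping$organ %in% organs,
                                     c("organ", "effect")])
  t[order(t$organ, t$effect), , drop = FALSE]
}

#' Score predictions against the in vivo observation registry
#'
#' The evaluation universe is the set of (substance, organ, effect) triples
#' whose effect category is reachable by at least one endpoint of the active
#' mapping — the test system is not scored on endpoints it cannot express
#' (set `include_unmapped = TRUE`, or `score_unmapped_effects` in the
#' config, to keep unreachable observed effects as automatic misses).
#' An effect absent from a substance's in vivo profile is treated as
#' observed-negative. Indicative concordance is the percentage of
#' observed-positive triples that are predicted positive; negative agreement
#' is the percentage of observed-negative triples with no in vitro
#' indication.
#'
#' @param predicted `prediction_set` (already thresholded).
#' @param observed `in_vivo_profile`.
#' @param mapping `effect_mapping` defining the reachable universe (ignored
#'   when `targets` is given).
#' @param targets optional explicit universe: data.frame with `organ`,
#'   `effect`. Supplying a common universe makes scopes directly comparable.
#' @param organs organs to evaluate.
#' @param substances substances to evaluate; defaults to those in `observed`.
#' @param include_unmapped keep observed effects with no mapped predictor in
#'   the denominator as automatic misses.
#' @return `concordance_report`: counts (`n_pos`, `n_hit`, `n_neg`,
#'   `n_correct_neg`), raw percentages (`indicative_concordance`,
#'   `negative_agreement`) and the per-triple `audit` table.
#' @export
compute_concordance <- function(predicted, observed, mapping = NULL,
                                targets = NULL,
                                organs = c("liver", "kidney"),
                                substances = NULL,
                                include_unmapped = FALSE) {
  if (is.null(targets)) {
    if (is.null(mapping)) {
      tc_stop("supply a mapping or an explicit targets table",
              "toxconcord_input_error")
    }
    targets <- mapping_targets(mapping, organs)
  } else {
    targets <- unique(as.data.frame(targets)[, c("organ", "effect")])
    targets <- targets[targets$organ %in% organs, , drop = FALSE]
  }
  observed <- as.data.frame(observed)
  predicted <- as.data.frame(predicted)
  substances <- substances %||% unique(observed$substance)

  if (include_unmapped && length(substances)) {
    extra <- unique(observed[observed$organ %in% organs &
                               observed$substance %in% substances,
                             c("organ", "effect")])
    targets <- unique(rbind(targets, extra))
  }

  if (length(substances) == 0 || nrow(targets) == 0) {
    if (nrow(targets) == 0) {
      warning("empty evaluation universe: no mapped in vivo effects",
              call. = FALSE)
    }
    audit <- data.frame(substance = character(0), organ = character(0),
                        effect = character(0), observed = logical(0),
                        predicted = logical(0), grade = character(0),
                        endpoints = character(0))
    return(new_concordance_report(0, 0, 0, 0, audit))
  }

  audit <- merge(data.frame(substance = substances), targets, by = NULL)
  obs_key <- paste(observed$substance, observed$organ, observed$effect,
                   sep = "\r")
  pred_key <- if (nrow(predicted)) paste(predicted$substance, predicted$organ,
                                         predicted$effect, sep = "\r")
              else character(0)
  key <- paste(audit$substance, audit$organ, audit$effect, sep = "\r")
  audit$observed <- key %in% obs_key
  hit <- match(key, pred_key)
  audit$predicted <- !is.na(hit)
  audit$grade <- ifelse(audit$predicted, predicted$grade[hit], "none")
  audit$endpoints <- ifelse(audit$predicted, predicted$endpoints[hit], "")
  audit <- audit[order(audit$substance, audit$organ, audit$effect), ]
  rownames(audit) <- NULL

  new_concordance_report(
    n_pos = sum(audit$observed),
    n_hit = sum(audit$observed & audit$predicted),
    n_neg = sum(!audit$observed),
    n_correct_neg = sum(!audit$observed & !audit$predicted),
    audit = audit)
}

new_concordance_report <- function(n_pos, n_hit, n_neg, n_correct_neg, audit,
                                   scope = NA_character_,
                                   threshold = NA_character_) {
  structure(list(
    scope = scope, threshold = threshold,
    n_pos = n_pos, n_hit = n_hit,
    indicative_concordance = if (n_pos > 0) 100 * n_hit / n_pos else NA_real_,
    n_neg = n_neg, n_correct_neg = n_correct_neg,
    negative_agreement = if (n_neg > 0) 100 * n_correct_neg / n_neg
                         else NA_real_,
    audit = audit), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>")
  if (!is.na(x$scope)) cat(sprintf(" scope=%s threshold=%s", x$scope, x$threshold))
  cat("\n")
  cat(sprintf("  indicative concordance: %s%% (%d of %d observed-positive)\n",
              if (is.na(x$indicative_concordance)) "NA"
              else round(x$indicative_concordance), x$n_hit, x$n_pos))
  cat(sprintf("  negative agreement:     %s%% (%d of %d observed-negative)\n",
              if (is.na(x$negative_agreement)) "NA"
              else round(x$negative_agreement), x$n_correct_neg, x$n_neg))
  invisible(x)
}

#' @export
summary.concordance_report <- function(object, ...) {
  as.data.frame(object[c("scope", "threshold", "n_pos", "n_hit",
                         "indicative_concordance", "n_neg", "n_correct_neg",
                         "negative_agreement")])
}

#' Sweep evidence thresholds across evaluation scopes
#'
#' Runs the mapping and concordance engine for every combination of scope
#' (protein per cell line and combined; transcript per input panel and
#' combined; protein + transcript combined) and evidence threshold (at least
#' medium, at least strong, very strong only) — 7 x 3 = 21 reports for the
#' full design. Each scope keeps its own evaluation universe: single-cell
#' line protein scopes are scored against their organ only, combined protein
#' scopes against both organs, transcript scopes against both organs, and
#' the overall combination against the union of both mappings' reachable
#' effects.
#'
#' @param protein_ev `marker_evidence` with a `cell_line` column
#'   (or `NULL` to skip protein scopes).
#' @param transcript_ev `category_evidence` with `input_scope` in
#'   `liver_panel` / `kidney_panel` / `combined` (or `NULL`).
#' @param observed `in_vivo_profile`.
#' @param protein_map,category_map effect mappings; default packaged tables.
#' @param config [tox_config()].
#' @param cell_line_organs named character vector assigning each protein
#'   cell line to its organ.
#' @return `concordance_sweep` data.frame: one row per scope x threshold
#'   with counts and raw percentages; per-row audits in `attr(, "audits")`.
#' @export
threshold_sweep <- function(protein_ev = NULL, transcript_ev = NULL, observed,
                            protein_map = load_ontology("protein_map"),
                            category_map = load_ontology("category_map"),
                            config = tox_config(),
                            cell_line_organs = c(HepaRG = "liver",
                                                 RPTEC = "kidney")) {
  thresholds <- c("medium", "strong", "very_strong")
  scopes <- list()
  if (!is.null(protein_ev)) {
    pe <- as.data.frame(protein_ev)
    lines <- intersect(names(cell_line_organs), unique(pe$cell_line))
    for (ln in lines) {
      scopes[[paste0("protein:", ln)]] <- list(
        evidence = pe[pe$cell_line == ln, ], mapping = protein_map,
        organs = unname(cell_line_organs[ln]),
        targets = mapping_targets(protein_map, cell_line_organs[ln]))
    }
    scopes[["protein:combined"]] <- list(
      evidence = pe, mapping = protein_map, organs = c("liver", "kidney"),
      targets = mapping_targets(protein_map))
  }
  if (!is.null(transcript_ev)) {
    te <- as.data.frame(transcript_ev)
    organ_line <- setNames(names(cell_line_organs), cell_line_organs)
    scope_label <- c(liver_panel = unname(organ_line["liver"]),
                     kidney_panel = unname(organ_line["kidney"]),
                     combined = "combined")
    for (sc in intersect(c("liver_panel", "kidney_panel", "combined"),
                         unique(te$input_scope))) {
      lab <- scope_label[sc]
      if (is.na(lab)) lab <- sc
      scopes[[paste0("mRNA:", lab)]] <- list(
        evidence = te[te$input_scope == sc, ], mapping = category_map,
        organs = c("liver", "kidney"),
        targets = mapping_targets(category_map))
    }
  }
  if (!is.null(protein_ev) && !is.null(transcript_ev) &&
      "combined" %in% unique(as.data.frame(transcript_ev)$input_scope)) {
    scopes[["combined:combined"]] <- list(
      combined = TRUE,
      targets = unique(rbind(mapping_targets(protein_map),
                             mapping_targets(category_map))))
  }
  if (length(scopes) == 0) {
    tc_stop("no evidence supplied to threshold_sweep", "toxconcord_input_error")
  }

  rows <- vector("list", 0L)
  audits <- list()
  for (sc_name in names(scopes)) {
    sc <- scopes[[sc_name]]
    for (th in thresholds) {
      pred <- if (isTRUE(sc$combined)) {
        pe <- as.data.frame(protein_ev)
        te <- as.data.frame(transcript_ev)
        combine_scopes(
          map_predictions(pe, protein_map, th),
          map_predictions(te[te$input_scope == "combined", ], category_map, th))
      } else {
        map_predictions(sc$evidence, sc$mapping, th, sc$organs)
      }
      rep <- compute_concordance(
        pred, observed, targets = sc$targets,
        include_unmapped = config$score_unmapped_effects)
      rep$scope <- sc_name
      rep$threshold <- th
      rows[[length(rows) + 1L]] <- summary(rep)
      audits[[paste(sc_name, th, sep = "|")]] <- rep$audit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "audits") <- audits
  class(out) <- c("concordance_sweep", "data.frame")
  out
}

#' @export
print.concordance_sweep <- function(x, ...) {
  cat("<concordance_sweep> indicative concordance % (negative agreement %), by threshold\n")
  df <- as.data.frame(x)
  wide <- sapply(c("medium", "strong", "very_strong"), function(th) {
    sub <- df[df$threshold == th, ]
    sprintf("%s (%s)",
            ifelse(is.na(sub$indicative_concordance), "NA",
                   round(sub$indicative_concordance)),
            ifelse(is.na(sub$negative_agreement), "NA",
                   round(sub$negative_agreement)))
  })
  if (is.null(dim(wide))) wide <- matrix(wide, nrow = 1,
                                         dimnames = list(NULL, names(wide)))
  rownames(wide) <- unique(df$scope)
  print(wide, quote = FALSE)
  invisible(x)
}
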