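# Delimited-file interfaces. All files are UTF-8 CSV with a mandatory header
# row; numeric fields tolerate decimal commas from German-locale spreadsheet
# exports and are normalized on read.

CT_COLUMNS <- c("sample_id", "cell_line", "substance", "concentration",
                "time", "group", "gene", "ct")
CT_GROUPS <- c("treated", "solvent_control", "untreated_control")

#' Read a replicate-level Ct table
#'
#' Expects the long format produced by exporting threshold-cycle values from
#' a qPCR instrument: one row per (sample, gene). Non-numeric Ct fields (for
#' example `"Undetermined"`) are kept and flagged in the logical `undetected`
#' column rather than dropped. An optional `is_housekeeping` column marks the
#' reference genes; it defaults to `FALSE`.
#'
#' @param path CSV file with columns `sample_id`, `cell_line`, `substance`,
#'   `concentration`, `time`, `group`, `gene`, `ct` (+ optional
#'   `is_housekeeping`).
#' @return a `ct_table` data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read_csv_checked(path, "Ct table")
  require_columns(df, CT_COLUMNS, "Ct table")
  raw_ct <- df$ct
  df$ct <- parse_numeric(raw_ct)
  df$undetected <- is.na(df$ct)
  df$concentration <- parse_numeric(df$concentration)
  df$time <- parse_numeric(df$time)
  df$is_housekeeping <- if ("is_housekeeping" %in% names(df))
    parse_logical(df$is_housekeeping) else FALSE
  as_ct_table(df)
}

#' Construct / validate a Ct table
#'
#' @param df data.frame with the [read_ct_table()] columns (plus `undetected`
#'   and `is_housekeeping`, added when absent).
#' @return validated `ct_table`.
#' @export
as_ct_table <- function(df) {
  if (!"undetected" %in% names(df)) df$undetected <- is.na(df$ct)
  if (!"is_housekeeping" %in% names(df)) df$is_housekeeping <- FALSE
  require_columns(df, c(CT_COLUMNS, "undetected", "is_housekeeping"), "Ct table")
  bad_group <- setdiff(unique(df$group), CT_GROUPS)
  if (length(bad_group)) {
    tc_stop(sprintf("unknown group label(s): %s (valid: %s)",
                    paste(bad_group, collapse = ", "),
                    paste(CT_GROUPS, collapse = ", ")),
            "toxconcord_schema_error")
  }
  det <- !df$undetected
  if (any(det & (df$ct <= 0 | df$ct > 45))) {
    tc_stop("detected Ct values must lie in (0, 45] cycles",
            "toxconcord_input_error")
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a Ct table (round-trip safe)
#'
#' Undetected wells are serialized as `"Undetermined"`, mirroring instrument
#' exports, so that write-then-read is the identity.
#'
#' @param x `ct_table`
#' @param path output CSV path
#' @export
write_ct_table <- function(x, path) {
  out <- as.data.frame(x)
  out$ct <- ifelse(out$undetected, "Undetermined", format_num(out$ct))
  out$undetected <- NULL
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

format_num <- function(x) format(x, trim = TRUE, digits = 15, scientific = FALSE)

read_csv_checked <- function(path, what) {
  if (!file.exists(path)) {
    tc_stop(sprintf("%s file not found: %s", what, path), "toxconcord_input_error")
  }
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) {
                   tc_stop(sprintf("%s file %s could not be parsed: %s",
                                   what, path, conditionMessage(e)),
                           "toxconcord_input_error")
                 })
  if (nrow(df) == 0) {
    tc_stop(sprintf("%s file %s contains no records", what, path),
            "toxconcord_input_error")
  }
  df
}

extdata <- function(file) {
  system.file("extdata", file, package = "toxconcord", mustWork = TRUE)
}

#' Controlled vocabulary of in vivo effect categories
#'
#' @return data.frame with columns `organ`, `effect`: the curated liver and
#'   kidney effect categories the ontologies may reference.
#' @export
effect_vocabulary <- function() {
  read.csv(extdata("effect_vocabulary.csv"), stringsAsFactors = FALSE)
}

check_vocabulary <- function(effects, organs, vocab = effect_vocabulary()) {
  keys <- paste(organs, effects, sep = "\r")
  ok <- keys %in% paste(vocab$organ, vocab$effect, sep = "\r")
  ok[is.na(effects) | effects == ""] <- TRUE
  if (any(!ok)) {
    bad <- unique(paste0(effects[!ok], " (", organs[!ok], ")"))
    tc_stop(sprintf(
      "unknown in vivo effect categor%s: %s\nValid terms: %s",
      if (length(bad) > 1) "ies" else "y",
      paste(bad, collapse = "; "),
      paste(sort(unique(vocab$effect)), collapse = "; ")),
      "toxconcord_vocabulary_error")
  }
  invisible(TRUE)
}

#' Load an effect ontology
#'
#' Three curated ontologies drive the concordance engine and ship with the
#' package; each can be overridden by a user file with the same columns.
#' \describe{
#'   \item{`in_vivo`}{per-substance in vivo effect profiles
#'     (`substance`, `organ`, `effect`): the observation registry.}
#'   \item{`protein_map`}{protein cellular function to in vivo effects
#'     (`cellular_function`, `organ`, `effect`); an empty `effect` field
#'     records an endpoint with no in vivo counterpart.}
#'   \item{`category_map`}{pathway-analysis category (or comma-separated
#'     category combination, which fires only when all members pass the
#'     evidence threshold) to in vivo effects
#'     (`categories`, `organ`, `effect`).}
#' }
#' Every non-empty target effect must belong to [effect_vocabulary()].
#'
#' @param kind one of `"in_vivo"`, `"protein_map"`, `"category_map"`.
#' @param path optional CSV overriding the packaged table.
#' @return for `in_vivo` an `in_vivo_profile` data.frame; otherwise an
#'   `effect_mapping` data.frame with columns `endpoint`, `members`
#'   (list-column of member categories), `organ`, `effect`.
#' @examples
#' m <- load_ontology("protein_map")
#' subset(m, endpoint == "Hypoxia")  # an endpoint with no in vivo target
#' @export
load_ontology <- function(kind = c("in_vivo", "protein_map", "category_map"),
                          path = NULL) {
  kind <- match.arg(kind)
  path <- path %||% extdata(switch(kind,
    in_vivo = "in_vivo_profiles.csv",
    protein_map = "protein_effect_map.csv",
    category_map = "category_effect_map.csv"))
  df <- read_csv_checked(path, sprintf("ontology (%s)", kind))
  if (kind == "in_vivo") {
    require_columns(df, c("substance", "organ", "effect"), "in vivo profile")
    check_vocabulary(df$effect, df$organ)
    class(df) <- c("in_vivo_profile", "data.frame")
    return(df)
  }
  key_col <- if (kind == "protein_map") "cellular_function" else "categories"
  require_columns(df, c(key_col, "organ", "effect"), sprintf("%s ontology", kind))
  check_vocabulary(df$effect, df$organ)
  out <- data.frame(endpoint = df[[key_col]], organ = df$organ,
                    effect = ifelse(is.na(df$effect) | df$effect == "",
                                    NA_character_, df$effect),
                    stringsAsFactors = FALSE)
  out$members <- if (kind == "category_map")
    strsplit(out$endpoint, ", ", fixed = TRUE) else as.list(out$endpoint)
  structure(out, class = c("effect_mapping", "data.frame"), kind = kind)
}

#' Organ-relevant pathway-analysis categories
#'
#' The packaged whitelist holds the liver and kidney disease-or-function
#' categories retained when annotation exports are filtered; extend it by
#' passing extra terms to [filter_organ_categories()].
#'
#' @return character vector of category names.
#' @export
category_whitelist <- function() {
  read.csv(extdata("ipa_category_whitelist.csv"), stringsAsFactors = FALSE)$category
}

#' Marker-to-cellular-function lookup for the 8-marker protein panel
#'
#' @return data.frame with columns `marker`, `cellular_function`.
#' @export
protein_marker_functions <- function() {
  read.csv(extdata("protein_markers.csv"), stringsAsFactors = FALSE)
}

#' Read a long-format protein panel file
#'
#' One row per replicate measurement, as percent of the solvent control.
#' Missing `cellular_function` is filled from [protein_marker_functions()].
#'
#' @param path CSV with columns `marker`, `cell_line`, `substance`,
#'   `concentration`, `time`, `replicate`, `value` (+ optional
#'   `cellular_function`).
#' @return `protein_panel` data.frame.
#' @export
read_protein_panel <- function(path) {
  df <- read_csv_checked(path, "protein panel")
  as_protein_panel(df)
}

#' @rdname read_protein_panel
#' @param df in-memory data.frame in the same layout.
#' @export
as_protein_panel <- function(df) {
  require_columns(df, c("marker", "cell_line", "substance", "concentration",
                        "time", "replicate", "value"), "protein panel")
  df$value <- parse_numeric(df$value)
  df$concentration <- parse_numeric(df$concentration)
  df$time <- parse_numeric(df$time)
  if (any(is.na(df$value) | df$value <= 0)) {
    tc_stop("protein panel values must be positive percent-of-control numbers",
            "toxconcord_input_error")
  }
  if (!"cellular_function" %in% names(df)) {
    lut <- protein_marker_functions()
    df$cellular_function <- lut$cellular_function[match(df$marker, lut$marker)]
    if (anyNA(df$cellular_function)) {
      tc_stop(sprintf("unknown marker(s): %s (add a cellular_function column)",
                      paste(unique(df$marker[is.na(df$cellular_function)]),
                            collapse = ", ")),
              "toxconcord_schema_error")
    }
  }
  class(df) <- c("protein_panel", "data.frame")
  df
}

#' Read a pathway-analysis annotation export
#'
#' The spreadsheet export of a disease-or-function analysis: one row per
#' annotation with its category and overlap p-value.
#'
#' @param path CSV with columns `substance`, `input_scope`, `category`,
#'   `annotation`, `p_overlap` (+ optional `n_deg`, `deg_names`).
#' @return `annotation_table` data.frame.
#' @export
read_annotation_export <- function(path) {
  df <- read_csv_checked(path, "annotation export")
  as_annotation_table(df)
}

#' @rdname read_annotation_export
#' @param df in-memory data.frame in the same layout.
#' @export
as_annotation_table <- function(df) {
  require_columns(df, c("substance", "input_scope", "category", "annotation",
                        "p_overlap"), "annotation export")
  df$p_overlap <- parse_numeric(df$p_overlap)
  if (any(is.na(df$p_overlap) | df$p_overlap <= 0 | df$p_overlap > 1)) {
    tc_stop("p_overlap must lie in (0, 1]", "toxconcord_input_error")
  }
  if (any(is.na(df$category) | df$category == "")) {
    tc_stop("annotation records need a non-empty category",
            "toxconcord_input_error")
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read a two-column pathway catalog
#'
#' @param path CSV with columns `pathway`, `gene`.
#' @param background optional character vector of all panel genes; defaults
#'   to the union of catalog genes.
#' @return `pathway_catalog`: list with `sets` (named list of gene sets) and
#'   `background`.
#' @export
read_pathway_catalog <- function(path, background = NULL) {
  df <- read_csv_checked(path, "pathway catalog")
  require_columns(df, c("pathway", "gene"), "pathway catalog")
  pathway_catalog(split(df$gene, df$pathway), background)
}

#' @rdname read_pathway_catalog
#' @param sets named list of gene symbol vectors.
#' @export
pathway_catalog <- function(sets, background = NULL) {
  sets <- lapply(sets, unique)
  background <- unique(background %||% unlist(sets, use.names = FALSE))
  stray <- setdiff(unlist(sets, use.names = FALSE), background)
  if (length(stray)) {
    tc_stop(sprintf("pathway genes absent from the background: %s",
                    paste(stray, collapse = ", ")), "toxconcord_input_error")
  }
  structure(list(sets = sets, background = background),
            class = "pathway_catalog")
}
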