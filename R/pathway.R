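# DEG calling, percentage-of-DEG pathway summaries and the hypergeometric
# overlap statistic behind overrepresentation p-values.

#' Call differentially expressed genes
#'
#' A gene is a DEG when its absolute fold regulation reaches the threshold
#' (inclusive) and its t-test p-value is below alpha (strict). Genes whose
#' replicates were fully censored never qualify.
#'
#' @param expr `expression_table` from [quantify_expression()].
#' @param fc_threshold fold-regulation threshold (`|FR| >= fc_threshold`).
#' @param alpha significance level (`p < alpha`).
#' @return character vector of DEG symbols (unique).
#' @export
call_deg <- function(expr, fc_threshold = 2, alpha = 0.05) {
  require_columns(expr, c("gene", "fold_regulation", "p_value"),
                  "expression table")
  censored <- if ("censored_all" %in% names(expr)) expr$censored_all else FALSE
  hit <- abs(expr$fold_regulation) >= fc_threshold &
    !is.na(expr$p_value) & expr$p_value < alpha & !censored
  unique(expr$gene[hit])
}

#' Percentage of DEG per pathway
#'
#' For each pathway, the share of its genes that are differentially
#' expressed. DEG outside the catalog's background are ignored with a
#' warning (they cannot be attributed to any pathway).
#'
#' @param deg character vector of DEG symbols.
#' @param catalog [pathway_catalog()].
#' @return `deg_summary` data.frame: `pathway`, `n_genes`, `n_deg`,
#'   `pct_deg`.
#' @examples
#' cat <- pathway_catalog(list(steatosis = letters[1:20]))
#' pct_deg(letters[1:11], cat)$pct_deg  # 55
#' @export
pct_deg <- function(deg, catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  stray <- setdiff(deg, catalog$background)
  if (length(stray)) {
    warning(sprintf("ignoring %d DEG outside the panel background: %s",
                    length(stray), paste(stray, collapse = ", ")),
            call. = FALSE)
    deg <- intersect(deg, catalog$background)
  }
  out <- data.frame(
    pathway = names(catalog$sets),
    n_genes = vapply(catalog$sets, length, integer(1)),
    n_deg = vapply(catalog$sets, function(s) length(intersect(s, deg)),
                   integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$pct_deg <- 100 * out$n_deg / out$n_genes
  class(out) <- c("deg_summary", "data.frame")
  out
}

#' Overrepresentation p-value of a gene-set overlap
#'
#' Right-tail hypergeometric probability of drawing at least the observed
#' overlap between a DEG list and a predefined gene set from a finite
#' background — the overlap statistic used by pathway-overrepresentation
#' tools. Provided as a transparent stand-in for commercial annotation
#' engines so that synthetic end-to-end runs need no external service; it
#' does not reproduce any curated knowledge base.
#'
#' @param deg,gene_set,background character vectors of gene symbols;
#'   `deg` and `gene_set` must be subsets of `background`.
#' @return `P(overlap >= observed)`.
#' @examples
#' bg <- paste0("g", 1:20)
#' fisher_overlap(bg[1:5], bg[1:5], bg)  # 1 / choose(20, 5)
#' @export
fisher_overlap <- function(deg, gene_set, background) {
  deg <- unique(deg); gene_set <- unique(gene_set)
  background <- unique(background)
  if (length(setdiff(deg, background)) ||
      length(setdiff(gene_set, background))) {
    tc_stop("deg and gene_set must be subsets of the background",
            "toxconcord_domain_error")
  }
  overlap <- length(intersect(deg, gene_set))
  phyper(overlap - 1, length(gene_set),
         length(background) - length(gene_set), length(deg),
         lower.tail = FALSE)
}
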