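# Delta-delta-Ct quantification: censoring, housekeeping normalization,
# relative expression, fold regulation and per-gene significance.

#' Censor threshold-cycle values at a detection cutoff
#'
#' Ct values above the cutoff — and undetected wells (`NA`) — carry no
#' reliable quantitative signal and are replaced by the cutoff itself, the
#' most conservative detectable value.
#'
#' @param ct numeric Ct values; `NA` encodes an undetected well.
#' @param cutoff censoring cutoff in cycles.
#' @return numeric vector with attribute `censored` (logical) marking
#'   replaced entries.
#' @examples
#' censor_ct(c(28.4, 37.1, NA))
#' @export
censor_ct <- function(ct, cutoff = 35) {
  censored <- is.na(ct) | ct > cutoff
  out <- ifelse(censored, cutoff, ct)
  attr(out, "censored") <- censored
  out
}

#' Housekeeping-normalized Ct (delta-Ct) for one sample
#'
#' Subtracts the arithmetic mean Ct of the reference (housekeeping) genes
#' from each gene's Ct.
#'
#' @param sample data.frame with columns `gene`, `ct` — one sample's panel.
#' @param reference_genes character vector of housekeeping gene symbols; all
#'   must be present in the sample.
#' @param sample_id label used in error messages.
#' @return named numeric vector of delta-Ct values (all genes, references
#'   included).
#' @export
delta_ct <- function(sample, reference_genes, sample_id = "sample") {
  require_columns(sample, c("gene", "ct"), "Ct sample slice")
  missing <- setdiff(reference_genes, sample$gene)
  if (length(missing)) {
    tc_stop(sprintf("reference gene(s) %s absent in %s",
                    paste(missing, collapse = ", "), sample_id),
            "toxconcord_normalization_error")
  }
  hk_mean <- mean(sample$ct[sample$gene %in% reference_genes])
  setNames(sample$ct - hk_mean, sample$gene)
}

#' Relative expression of one gene from replicate delta-Ct values
#'
#' Per-replicate delta-delta-Ct values are treated-minus-control differences:
#' replicate-paired when the two groups have equal size (the per-experiment
#' control design), otherwise each treated replicate minus the control mean.
#' Relative expression is `2^-ddCt`; the p-value is a two-sided one-sample
#' t-test of the per-replicate ddCt values against 0 (log2 scale).
#'
#' @param treated,control numeric delta-Ct replicates.
#' @return one-row data.frame: `mean_ddct`, `fold_change`, `fold_regulation`,
#'   `p_value`, `n_treated`, `n_control`, `paired`.
#' @examples
#' ddct_expression(c(4, 4, 4), c(5, 5, 5))  # fold change 2
#' @export
ddct_expression <- function(treated, control) {
  if (length(treated) < 1 || length(control) < 1) {
    tc_stop("at least one treated and one control replicate are required",
            "toxconcord_missing_data_error")
  }
  paired <- length(treated) == length(control)
  dd <- if (paired) treated - control else treated - mean(control)
  mean_ddct <- mean(dd)
  fc <- 2^(-mean_ddct)
  p <- NA_real_
  if (length(treated) >= 2 && length(control) >= 2) {
    p <- if (sd(dd) == 0) {
      if (mean_ddct == 0) 1 else 0  # noise-free limit
    } else {
      t.test(dd, mu = 0)$p.value
    }
  }
  data.frame(mean_ddct = mean_ddct, fold_change = fc,
             fold_regulation = fold_regulation(fc), p_value = p,
             n_treated = length(treated), n_control = length(control),
             paired = paired)
}

#' Fold regulation: the signed representation of a fold change
#'
#' Equal to the fold change when it is at least 1, and to the negative
#' inverse of the fold change otherwise, so that a 4-fold repression reads
#' -4 rather than 0.25.
#'
#' @param fold_change positive ratio(s).
#' @return signed fold regulation, `|fr| >= 1`.
#' @examples
#' fold_regulation(c(2, 0.5, 1))  #  2 -2  1
#' @export
fold_regulation <- function(fold_change) {
  if (any(!is.finite(fold_change) | fold_change <= 0)) {
    tc_stop("fold change must be strictly positive",
            "toxconcord_domain_error")
  }
  ifelse(fold_change >= 1, fold_change, -1 / fold_change)
}

#' Cross-platform quality-control range check
#'
#' Fold changes for the same gene measured on the profiler array and by
#' single-assay qPCR must agree within a tolerance fold ratio.
#'
#' @param fc_array,fc_rtqpcr positive fold changes from the two platforms.
#' @param tolerance_fold maximal accepted ratio between them.
#' @return logical: `TRUE` when the two values are within range.
#' @export
qc_range_check <- function(fc_array, fc_rtqpcr, tolerance_fold = 3) {
  if (any(c(fc_array, fc_rtqpcr, tolerance_fold) <= 0) ||
      any(!is.finite(c(fc_array, fc_rtqpcr, tolerance_fold)))) {
    tc_stop("fold changes and tolerance must be strictly positive",
            "toxconcord_domain_error")
  }
  pmax(fc_array, fc_rtqpcr) / pmin(fc_array, fc_rtqpcr) <= tolerance_fold
}

#' Quantify a Ct table into a per-gene expression table
#'
#' The full array workflow: Ct censoring at the configured cutoff,
#' delta-Ct normalization to the arithmetic mean of the housekeeping genes,
#' and delta-delta-Ct of each treated condition against its matching control
#' group (same cell line and exposure time). Genes censored in every treated
#' and every control replicate are reported with fold change 1 and flagged
#' `censored_all` — the ratio of two censored values is uninformative, and
#' such genes are excluded from DEG calling.
#'
#' @param ct `ct_table` (see [read_ct_table()]).
#' @param config [tox_config()].
#' @param reference_genes housekeeping symbols; defaults to the genes marked
#'   `is_housekeeping` in the table.
#' @param control_group group label of the reference condition
#'   (`"untreated_control"` for array quantification).
#' @param logger optional internal log collector.
#' @return `expression_table` data.frame: one row per
#'   (substance, cell_line, concentration, time, gene) with `fold_change`,
#'   `fold_regulation`, `p_value`, `mean_ddct`, `n_replicates`,
#'   `censored_all`.
#' @export
quantify_expression <- function(ct, config = tox_config(),
                                reference_genes = NULL,
                                control_group = "untreated_control",
                                logger = NULL) {
  ct <- as_ct_table(as.data.frame(ct))
  log <- if (is.null(logger)) function(...) invisible() else logger$log
  log("censor_ct: cutoff %g cycles", config$ct_cutoff)
  cens <- censor_ct(ct$ct, config$ct_cutoff)
  ct$censored <- attr(cens, "censored")
  ct$ct <- as.numeric(cens)

  if (is.null(reference_genes)) {
    reference_genes <- unique(ct$gene[ct$is_housekeeping])
  }
  if (length(reference_genes) == 0) {
    tc_stop("no housekeeping genes: mark is_housekeeping or pass reference_genes",
            "toxconcord_normalization_error")
  }

  # per-sample delta-Ct
  ct$dct <- NA_real_
  for (sid in unique(ct$sample_id)) {
    idx <- ct$sample_id == sid
    dct <- delta_ct(ct[idx, c("gene", "ct")], reference_genes, sid)
    ct$dct[idx] <- dct[match(ct$gene[idx], names(dct))]
  }

  controls <- ct[ct$group == control_group, ]
  treated <- ct[ct$group == "treated", ]
  if (nrow(treated) == 0 || nrow(controls) == 0) {
    tc_stop(sprintf("need treated samples and '%s' samples", control_group),
            "toxconcord_missing_data_error")
  }

  key <- unique(treated[, c("substance", "cell_line", "concentration", "time")])
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(key))) {
    k <- key[i, ]
    tr <- treated[treated$substance == k$substance &
                  treated$cell_line == k$cell_line &
                  treated$concentration == k$concentration &
                  treated$time == k$time, ]
    co <- controls[controls$cell_line == k$cell_line &
                   controls$time == k$time, ]
    if (nrow(co) == 0) {
      tc_stop(sprintf("no %s samples for cell line %s at %g h",
                      control_group, k$cell_line, k$time),
              "toxconcord_missing_data_error")
    }
    tr_samples <- sort(unique(tr$sample_id))
    co_samples <- sort(unique(co$sample_id))
    for (g in unique(tr$gene[!tr$is_housekeeping])) {
      tg <- tr[tr$gene == g, ]
      cg <- co[co$gene == g, ]
      if (nrow(cg) == 0) next
      tg <- tg[order(match(tg$sample_id, tr_samples)), ]
      cg <- cg[order(match(cg$sample_id, co_samples)), ]
      all_cens <- all(tg$censored) && all(cg$censored)
      if (all_cens) {
        log("quantify: gene %s fully censored for %s/%s [reason=all_censored]",
            g, k$substance, k$cell_line)
        res <- data.frame(mean_ddct = 0, fold_change = 1, fold_regulation = 1,
                          p_value = NA_real_, n_treated = nrow(tg),
                          n_control = nrow(cg), paired = TRUE)
      } else {
        res <- ddct_expression(tg$dct, cg$dct)
      }
      rows[[length(rows) + 1L]] <- cbind(
        k, gene = g, res[, c("fold_change", "fold_regulation", "p_value",
                             "mean_ddct")],
        n_replicates = res$n_treated, censored_all = all_cens,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d gene measurements, %d substance(s), %d cell line(s)\n",
              nrow(x), length(unique(x$substance)),
              length(unique(x$cell_line))))
  NextMethod()
}
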