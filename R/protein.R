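# Protein-marker panel: bootstrap significance against the solvent control
# and ordinal grading of per-marker evidence.

#' Percentile-bootstrap test of a panel mean against the solvent control
#'
#' Resamples the replicate values with replacement and locates the null
#' value in the bootstrap distribution of the mean. The default
#' `"percentile"` method doubles the fraction of resampled means on the far
#' side of the null (capped at 1); `"null_resampling"` recentres the data at
#' the null first and reports the fraction of resampled means at least as
#' displaced as the observed mean. With very few replicates both p-values
#' are coarse (the resample distribution of n values has at most
#' `choose(2n-1, n)` atoms) and should be read as descriptive — grading
#' therefore never gates on them.
#'
#' Replicates are sorted before resampling, so the p-value is invariant to
#' replicate order and fully reproducible under a fixed seed.
#'
#' @param replicates percent-of-control values (>= 3).
#' @param null_value no-effect value, 100 percent.
#' @param n_boot number of resamples (>= 1000).
#' @param seed integer seed for the private RNG stream; `NULL` uses (and
#'   advances) the caller's stream.
#' @param method `"percentile"` (default) or `"null_resampling"`.
#' @return two-sided bootstrap p-value.
#' @examples
#' bootstrap_test(c(300, 310, 290), seed = 1)
#' @export
bootstrap_test <- function(replicates, null_value = 100, n_boot = 10000,
                           seed = NULL,
                           method = c("percentile", "null_resampling")) {
  method <- match.arg(method)
  if (length(replicates) < 3) {
    tc_stop("bootstrap_test needs at least 3 replicates",
            "toxconcord_missing_data_error")
  }
  if (n_boot < 1000) {
    tc_stop("n_boot must be at least 1000", "toxconcord_config_error")
  }
  x <- sort(as.numeric(replicates))
  m <- mean(x)
  if (all(x == null_value)) return(1)
  boot_means <- function(v) {
    colMeans(matrix(sample(v, length(v) * n_boot, replace = TRUE),
                    nrow = length(v)))
  }
  with_seed(seed, {
    if (method == "percentile") {
      if (m == null_value) return(1)
      bm <- boot_means(x)
      far <- if (m > null_value) mean(bm <= null_value) else mean(bm >= null_value)
      min(1, 2 * far)
    } else {
      bm <- boot_means(x - m + null_value)
      mean(abs(bm - null_value) >= abs(m - null_value) - 1e-12)
    }
  })
}

#' Grade a protein marker from its condition means
#'
#' The evidence matrix over the marker's exposure conditions
#' (concentration x time cells, means over replicates):
#' very_strong — at least 2 conditions above the upper bound (> 200%);
#' strong — 1 condition above the upper bound, or at least 2 in the medium
#' band (150, 200]; medium — at least 1 condition in the medium band;
#' otherwise none. Decreases below the control never contribute: every
#' marker readout is an increase-type endpoint.
#'
#' @param condition_means percent-of-control means, one per condition (1-4).
#' @param bounds lower and upper band bounds, default `c(150, 200)`.
#' @return a single evidence grade (ordered factor).
#' @examples
#' grade_protein(c(247, 120, 110, 95))   # strong
#' grade_protein(c(210, 230, 160, 140))  # very_strong
#' @export
grade_protein <- function(condition_means, bounds = c(150, 200)) {
  if (length(condition_means) < 1) {
    tc_stop("at least one condition mean is required",
            "toxconcord_missing_data_error")
  }
  n_hi <- sum(condition_means > bounds[2])
  n_mid <- sum(condition_means > bounds[1] & condition_means <= bounds[2])
  g <- if (n_hi >= 2) "very_strong"
  else if (n_hi >= 1 || n_mid >= 2) "strong"
  else if (n_mid >= 1) "medium"
  else "none"
  evidence_grade(g)
}

#' Graded evidence per marker and substance
#'
#' Averages replicates per condition (concentration x time), applies the
#' grading matrix, and reports a bootstrap p-value per condition alongside
#' (it does not gate the grade).
#'
#' @param panel `protein_panel` (see [read_protein_panel()]).
#' @param config [tox_config()]; supplies the grade bounds, `n_boot` and the
#'   seed for reproducible bootstrap p-values.
#' @param bootstrap compute per-condition bootstrap p-values (set `FALSE`
#'   to skip the resampling when only grades are needed).
#' @return `marker_evidence` data.frame: one row per
#'   (substance, cell_line, marker) with `cellular_function`, `grade`,
#'   `n_conditions`, `max_condition_mean`, `min_boot_p`; the per-condition
#'   detail (mean, bootstrap p) is in `attr(, "conditions")`.
#' @export
marker_evidence <- function(panel, config = tox_config(), bootstrap = TRUE) {
  panel <- as_protein_panel(as.data.frame(panel))
  key <- unique(panel[, c("substance", "cell_line", "marker",
                          "cellular_function")])
  key <- key[order(key$substance, key$cell_line, key$marker), ]
  ev <- vector("list", nrow(key))
  cond_rows <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    k <- key[i, ]
    sub <- panel[panel$substance == k$substance &
                 panel$cell_line == k$cell_line &
                 panel$marker == k$marker, ]
    cond <- aggregate(value ~ concentration + time, sub, mean)
    cond <- cond[order(cond$concentration, cond$time), ]
    cond$n_replicates <- aggregate(value ~ concentration + time, sub, length)$value
    cond$boot_p <- NA_real_
    if (bootstrap) {
      for (j in seq_len(nrow(cond))) {
        reps <- sub$value[sub$concentration == cond$concentration[j] &
                          sub$time == cond$time[j]]
        if (length(reps) >= 3) {
          cond$boot_p[j] <- bootstrap_test(
            reps, 100, config$n_boot,
            seed = config$rng_seed + 131L * i + j)
        }
      }
    }
    g <- grade_protein(cond$value, config$protein_grade_bounds)
    ev[[i]] <- cbind(k, data.frame(
      grade = as.character(g), n_conditions = nrow(cond),
      max_condition_mean = max(cond$value),
      min_boot_p = if (all(is.na(cond$boot_p))) NA_real_
                   else min(cond$boot_p, na.rm = TRUE)),
      row.names = NULL)
    cond_rows[[i]] <- cbind(k, cond[, c("concentration", "time", "value",
                                        "n_replicates", "boot_p")],
                            row.names = NULL)
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  attr(out, "conditions") <- do.call(rbind, cond_rows)
  class(out) <- c("marker_evidence", "data.frame")
  out
}

#' OR-combine marker evidence across cell lines
#'
#' A positive prediction from either cell line is sufficient: per
#' (substance, cellular function) the combined grade is the maximum of the
#' contributing grades and supporting conditions are concatenated.
#' The operation is commutative, associative and idempotent.
#'
#' @param ... `marker_evidence` tables (typically one per cell line).
#' @param label `cell_line` label of the result.
#' @return combined `marker_evidence` with one row per
#'   (substance, cellular_function).
#' @export
combine_cell_lines <- function(..., label = "combined") {
  tabs <- list(...)
  all_ev <- do.call(rbind, lapply(tabs, function(t)
    as.data.frame(t)[, c("substance", "cellular_function", "grade",
                         "n_conditions", "max_condition_mean", "min_boot_p")]))
  key <- unique(all_ev[, c("substance", "cellular_function")])
  key <- key[order(key$substance, key$cellular_function), ]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    sub <- all_ev[all_ev$substance == k$substance &
                  all_ev$cellular_function == k$cellular_function, ]
    data.frame(substance = k$substance, cell_line = label,
               marker = NA_character_,
               cellular_function = k$cellular_function,
               grade = as.character(max(evidence_grade(sub$grade))),
               n_conditions = sum(sub$n_conditions),
               max_condition_mean = max(sub$max_condition_mean),
               min_boot_p = if (all(is.na(sub$min_boot_p))) NA_real_
                            else min(sub$min_boot_p, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  conds <- lapply(tabs, attr, "conditions")
  if (!any(vapply(conds, is.null, logical(1)))) {
    attr(out, "conditions") <- do.call(rbind, conds)
  }
  class(out) <- c("marker_evidence", "data.frame")
  out
}

#' @export
print.marker_evidence <- function(x, ...) {
  cat(sprintf("<marker_evidence> %d marker calls; grades: %s\n", nrow(x),
              paste(sprintf("%s=%d", grade_levels(),
                            tabulate(as.integer(evidence_grade(x$grade)),
                                     nbins = 4)),
                    collapse = " ")))
  NextMethod()
}
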