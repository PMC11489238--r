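# Viability screen: plate-reader normalization and selection of the highest
# non-cytotoxic concentration that feeds every downstream assay.

#' Normalize a dual-wavelength absorbance reading to percent of control
#'
#' Tetrazolium-reduction readouts are measured at a signal and a reference
#' wavelength; the blank's net absorbance is subtracted before relating the
#' treated net signal to the solvent control's net signal.
#'
#' @param a_signal,a_reference treated-well absorbance at the signal and
#'   reference wavelengths.
#' @param blank_signal,blank_reference cell-free blank absorbances.
#' @param control_net blank-corrected net absorbance of the solvent control.
#' @return viability in percent of the solvent control.
#' @examples
#' normalize_absorbance(0.9, 0.1, 0.05, 0.05, 0.8)  # 100%
#' @export
normalize_absorbance <- function(a_signal, a_reference, blank_signal,
                                 blank_reference, control_net) {
  if (any(control_net <= 0)) {
    tc_stop("solvent-control net absorbance must be positive",
            "toxconcord_degenerate_control_error")
  }
  100 * ((a_signal - a_reference) - (blank_signal - blank_reference)) / control_net
}

#' Normalize a fluorescence reading to percent of control
#'
#' @param signal treated-well fluorescence (RFU).
#' @param blank blank fluorescence.
#' @param control_net blank-corrected solvent-control fluorescence.
#' @return viability in percent of the solvent control.
#' @export
normalize_fluorescence <- function(signal, blank, control_net) {
  if (any(control_net <= 0)) {
    tc_stop("solvent-control net fluorescence must be positive",
            "toxconcord_degenerate_control_error")
  }
  100 * (signal - blank) / control_net
}

#' Select the highest non-cytotoxic concentration
#'
#' A concentration passes when the mean viability of *every* provided assay
#' strictly exceeds the threshold; the largest passing tested concentration
#' is returned. When even the maximum tested concentration passes, the result
#' is flagged `top_of_range` (the true non-cytotoxic maximum may lie beyond
#' the tested range).
#'
#' @param curves data.frame with columns `assay`, `concentration`,
#'   `viability` (replicate rows are averaged per assay x concentration);
#'   one substance and cell line at a time.
#' @param threshold percent viability that must be exceeded (strictly);
#'   exactly `threshold` fails.
#' @return list with `concentration` (the selection) and `top_of_range`.
#' @examples
#' cv <- data.frame(assay = "WST1", concentration = c(100, 300, 1000),
#'                  viability = c(95, 85, 60))
#' select_highest_noncytotoxic(cv)$concentration  # 300
#' @export
select_highest_noncytotoxic <- function(curves, threshold = 80) {
  require_columns(curves, c("assay", "concentration", "viability"),
                  "viability curve")
  if (nrow(curves) == 0) {
    tc_stop("no viability measurements provided", "toxconcord_input_error")
  }
  if (any(curves$viability < 0)) {
    tc_stop("viability must be non-negative", "toxconcord_input_error")
  }
  means <- aggregate(viability ~ assay + concentration, curves, mean)
  pass_by_conc <- tapply(means$viability > threshold, means$concentration, all)
  concs <- as.numeric(names(pass_by_conc))
  passing <- concs[pass_by_conc]
  if (length(passing) == 0) {
    tc_stop(sprintf(
      "no tested concentration keeps viability above %g%% in all assays; test a lower concentration range",
      threshold), "toxconcord_selection_error")
  }
  sel <- max(passing)
  list(concentration = sel, top_of_range = sel == max(concs))
}

#' Companion lower test concentration
#'
#' The second exposure concentration used throughout the study design:
#' one third (0.33x) of the highest non-cytotoxic concentration.
#'
#' @param c_high highest non-cytotoxic concentration.
#' @return `0.33 * c_high`.
#' @export
second_concentration <- function(c_high) {
  if (any(c_high < 0)) tc_stop("concentration must be non-negative",
                               "toxconcord_input_error")
  0.33 * c_high
}
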