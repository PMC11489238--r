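# Synthetic-data generator: inputs with the statistical structure the
# analysis assumes (Gaussian Ct noise on the cycle scale, lognormal protein
# noise on the percent scale, annotation exports with controllable category
# activity) plus in vivo profiles drawn so that the true indicative
# concordance equals a target value.

#' Define a simulation scenario
#'
#' Defaults mirror the study design: 6 substances, two cell lines (liver
#' and kidney), a 370-target liver array and an 84-target kidney array with
#' 5 shared housekeeping genes, 3 biological replicates with 0.25-cycle Ct
#' noise, and an 8-marker protein panel measured at 2 concentrations x
#' 2 timepoints x 3 replicates with lognormal noise (cv 0.3).
#'
#' @param n_substances number of test substances.
#' @param cell_lines named character vector: cell line -> organ.
#' @param n_target_genes named integer vector: targets per organ panel.
#' @param hk_genes housekeeping gene symbols shared by both panels.
#' @param n_replicates biological replicates per group.
#' @param replicate_sd Ct replicate noise (cycles).
#' @param frac_active_genes fraction of target genes with a true effect.
#' @param active_log2fc absolute true log2 fold change of active genes.
#' @param protein_cv coefficient of variation of protein replicates.
#' @param active_protein_pct true percent-of-control of an active marker's
#'   induced conditions (two of the four conditions).
#' @param frac_active_markers probability a marker is truly active for a
#'   substance and cell line.
#' @param frac_active_categories probability an annotation category is truly
#'   active for a substance and input panel.
#' @param target_concordance true indicative concordance the in vivo
#'   profiles are drawn to achieve (fraction).
#' @param positive_prevalence fraction of evaluable triples that are in vivo
#'   positive (clamped when the target requires it).
#' @param seed integer master seed; every stage derives a fixed offset
#'   stream from it.
#' @return `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_substances = 6,
                                cell_lines = c(HepaRG = "liver",
                                               RPTEC = "kidney"),
                                n_target_genes = c(liver = 370, kidney = 84),
                                hk_genes = c("ACTB", "B2M", "GAPDH",
                                             "HPRT1", "RPLP0"),
                                n_replicates = 3,
                                replicate_sd = 0.25,
                                frac_active_genes = 0.1,
                                active_log2fc = 2,
                                protein_cv = 0.3,
                                active_protein_pct = 250,
                                frac_active_markers = 0.4,
                                frac_active_categories = 0.4,
                                target_concordance = 0.75,
                                positive_prevalence = 0.5,
                                seed = 1L) {
  stopifnot(replicate_sd > 0, protein_cv >= 0,
            target_concordance >= 0, target_concordance <= 1,
            frac_active_markers >= 0, frac_active_markers <= 1,
            frac_active_categories >= 0, frac_active_categories <= 1)
  structure(list(
    n_substances = n_substances,
    substances = sprintf("S%02d", seq_len(n_substances)),
    cell_lines = cell_lines, n_target_genes = n_target_genes,
    hk_genes = hk_genes, n_replicates = n_replicates,
    replicate_sd = replicate_sd, frac_active_genes = frac_active_genes,
    active_log2fc = active_log2fc, protein_cv = protein_cv,
    active_protein_pct = active_protein_pct,
    frac_active_markers = frac_active_markers,
    frac_active_categories = frac_active_categories,
    target_concordance = target_concordance,
    positive_prevalence = positive_prevalence,
    seed = as.integer(seed)), class = "simulation_scenario")
}

panel_genes <- function(scenario, organ) {
  n <- scenario$n_target_genes[[organ]]
  sprintf("%s%03d", toupper(substr(organ, 1, 3)), seq_len(n))
}

# Per-gene true log2 fold changes, deterministic in the scenario seed.
true_log2fc <- function(scenario, organ) {
  genes <- panel_genes(scenario, organ)
  with_seed(scenario$seed + 100L + match(organ, c("liver", "kidney")), {
    m <- matrix(0, length(scenario$substances), length(genes),
                dimnames = list(scenario$substances, genes))
    active <- matrix(runif(length(m)) < scenario$frac_active_genes, nrow(m))
    signs <- matrix(sample(c(-1, 1), length(m), replace = TRUE), nrow(m))
    m[active] <- (signs * scenario$active_log2fc)[active]
    m
  })
}

#' Simulate a replicate-level Ct table for one organ panel
#'
#' Housekeeping Cts fluctuate around a fixed baseline identically in all
#' groups; a treated target gene's expected Ct is the control expectation
#' minus its true log2 fold change; replicate noise is Gaussian on the
#' cycle scale. The true effect matrix is attached as
#' `attr(, "true_log2fc")`.
#'
#' @param scenario [simulation_scenario()].
#' @param organ `"liver"` or `"kidney"` (selects panel and cell line).
#' @return `ct_table`.
#' @export
simulate_ct_table <- function(scenario, organ = c("liver", "kidney")) {
  organ <- match.arg(organ)
  line <- names(scenario$cell_lines)[scenario$cell_lines == organ][1]
  genes <- panel_genes(scenario, organ)
  lfc <- true_log2fc(scenario, organ)
  with_seed(scenario$seed + 300L + match(organ, c("liver", "kidney")), {
    base <- setNames(c(runif(length(genes), 22, 30),
                       runif(length(scenario$hk_genes), 19, 21)),
                     c(genes, scenario$hk_genes))
    all_genes <- names(base)
    is_hk <- all_genes %in% scenario$hk_genes
    one_sample <- function(sample_id, substance, group, conc) {
      mu <- base
      if (group == "treated") {
        mu[genes] <- mu[genes] - lfc[substance, genes]
      }
      data.frame(sample_id = sample_id, cell_line = line,
                 substance = substance, concentration = conc, time = 36,
                 group = group, gene = all_genes,
                 ct = mu + rnorm(length(mu), 0, scenario$replicate_sd),
                 is_housekeeping = is_hk, row.names = NULL)
    }
    rows <- list()
    for (r in seq_len(scenario$n_replicates)) {
      rows[[length(rows) + 1L]] <- one_sample(
        sprintf("%s_ctrl_r%d", line, r), "none", "untreated_control", 0)
    }
    for (s in scenario$substances) {
      for (r in seq_len(scenario$n_replicates)) {
        rows[[length(rows) + 1L]] <- one_sample(
          sprintf("%s_%s_r%d", line, s, r), s, "treated", 100)
      }
    }
    out <- do.call(rbind, rows)
    out$ct <- pmin(pmax(out$ct, 1), 45)
    out <- as_ct_table(out)
    attr(out, "true_log2fc") <- lfc
    out
  })
}

# Which markers are truly active, per substance and cell line.
protein_truth <- function(scenario) {
  markers <- protein_marker_functions()
  grid <- merge(merge(data.frame(substance = scenario$substances), markers,
                      by = NULL),
                data.frame(cell_line = names(scenario$cell_lines)), by = NULL)
  grid <- grid[order(grid$substance, grid$cell_line, grid$marker), ]
  rownames(grid) <- NULL
  with_seed(scenario$seed + 1000L, {
    grid$active <- runif(nrow(grid)) < scenario$frac_active_markers
  })
  grid
}

# True percent-of-control per condition: active markers are induced above
# the strong band in both high-concentration conditions.
condition_truth <- function(scenario, active) {
  if (active) c(scenario$active_protein_pct, scenario$active_protein_pct,
                130, 110)
  else rep(100, 4)
}

#' Simulate the long-format protein panel
#'
#' Replicate values are lognormal around each condition's true
#' percent-of-control with coefficient of variation `protein_cv`. The
#' marker activity truth is attached as `attr(, "truth")`.
#'
#' @param scenario [simulation_scenario()].
#' @return `protein_panel`.
#' @export
simulate_protein_panel <- function(scenario) {
  truth <- protein_truth(scenario)
  sdlog <- sqrt(log(1 + scenario$protein_cv^2))
  conds <- data.frame(concentration = c(100, 100, 33, 33),
                      time = c(36, 72, 36, 72))
  with_seed(scenario$seed + 4000L, {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tr <- condition_truth(scenario, truth$active[i])
      n <- scenario$n_replicates
      vals <- rlnorm(4 * n, meanlog = log(rep(tr, each = n)) - sdlog^2 / 2,
                     sdlog = sdlog)
      rows[[i]] <- data.frame(
        marker = truth$marker[i],
        cellular_function = truth$cellular_function[i],
        cell_line = truth$cell_line[i], substance = truth$substance[i],
        concentration = rep(conds$concentration, each = n),
        time = rep(conds$time, each = n),
        replicate = rep(seq_len(n), 4), value = vals, row.names = NULL)
    }
    out <- as_protein_panel(do.call(rbind, rows))
    attr(out, "truth") <- truth
    out
  })
}

# Which annotation categories are truly active, per substance and panel.
category_truth <- function(scenario, category_map = load_ontology("category_map")) {
  cats <- sort(unique(unlist(category_map$members)))
  grid <- expand.grid(substance = scenario$substances,
                      input_scope = c("liver_panel", "kidney_panel"),
                      category = cats, stringsAsFactors = FALSE)
  grid <- grid[order(grid$substance, grid$input_scope, grid$category), ]
  rownames(grid) <- NULL
  with_seed(scenario$seed + 2000L, {
    grid$active <- runif(nrow(grid)) < scenario$frac_active_categories
  })
  grid
}

#' Simulate pathway-analysis annotation exports
#'
#' Active categories receive annotations with overlap p-values below the
#' very-strong threshold; inactive categories receive clearly
#' non-significant annotations; a sprinkle of off-organ categories
#' exercises the organ filter. The combined scope is the concatenation of
#' both panel exports (its best p per category is their minimum).
#'
#' @param scenario [simulation_scenario()].
#' @param category_map mapping whose member categories populate the exports.
#' @return `annotation_table` with `input_scope` in
#'   liver_panel/kidney_panel/combined; truth in `attr(, "truth")`.
#' @export
simulate_annotation_exports <- function(scenario,
                                        category_map = load_ontology("category_map")) {
  truth <- category_truth(scenario, category_map)
  with_seed(scenario$seed + 5000L, {
    n <- nrow(truth)
    p1 <- ifelse(truth$active, 10^runif(n, -6, -3.5), runif(n, 0.06, 0.9))
    p2 <- ifelse(truth$active, 10^runif(n, -5, -3.4), runif(n, 0.06, 0.9))
    recs <- rbind(
      data.frame(truth[, c("substance", "input_scope", "category")],
                 annotation = paste0(truth$category, " annotation A"),
                 p_overlap = p1, row.names = NULL),
      data.frame(truth[, c("substance", "input_scope", "category")],
                 annotation = paste0(truth$category, " annotation B"),
                 p_overlap = p2, row.names = NULL))
    off <- data.frame(substance = scenario$substances,
                      input_scope = "liver_panel",
                      annotation = "Cardiac Necrosis annotation",
                      category = "Cardiac Necrosis",
                      p_overlap = 10^runif(scenario$n_substances, -5, -3))
    recs <- rbind(recs, off[, names(recs)])
    comb <- recs
    comb$input_scope <- "combined"
    out <- as_annotation_table(rbind(recs, unique(comb)))
    attr(out, "truth") <- truth
    out
  })
}

# Noise-free evidence tables implied by the generator's truth.
truth_evidence <- function(scenario, category_map) {
  pt <- protein_truth(scenario)
  pt$grade <- vapply(pt$active, function(a)
    as.character(grade_protein(condition_truth(scenario, a))), character(1))
  ct <- category_truth(scenario, category_map)
  comb <- aggregate(active ~ substance + category, ct, any)
  comb$input_scope <- "combined"
  ct <- rbind(ct[, c("substance", "input_scope", "category", "active")],
              comb[, c("substance", "input_scope", "category", "active")])
  ct$grade <- ifelse(ct$active, "very_strong", "none")
  list(protein = pt, category = ct)
}

#' Simulate a complete study bundle with known ground truth
#'
#' Generates every pipeline input (Ct tables, protein panel, annotation
#' exports, viability curves) and draws the in vivo effect profiles so that
#' the expected indicative concordance of the combined protein + transcript
#' evaluation at the medium threshold equals `target_concordance`:
#' conditional on a triple being observed-positive, it is ground-truth
#' predicted with probability exactly the target, independently across
#' triples.
#'
#' @param scenario [simulation_scenario()].
#' @param protein_map,category_map effect mappings (packaged defaults).
#' @param include_ct simulate the (large) Ct tables too; disable when only
#'   the evidence-to-concordance path is exercised.
#' @return list with `ct` (list liver/kidney or NULL), `protein_panel`,
#'   `annotations`, `viability`, `in_vivo`, and `truth` (activity tables,
#'   ground-truth prediction set, evaluation universe, `n_evaluable`,
#'   `n_pos`, `target_concordance`).
#' @export
simulate_study <- function(scenario = simulation_scenario(),
                           protein_map = load_ontology("protein_map"),
                           category_map = load_ontology("category_map"),
                           include_ct = TRUE) {
  tev <- truth_evidence(scenario, category_map)
  targets <- unique(rbind(mapping_targets(protein_map),
                          mapping_targets(category_map)))
  pred_truth <- combine_scopes(
    map_predictions(tev$protein, protein_map, "medium"),
    map_predictions(tev$category[tev$category$input_scope == "combined", ],
                    category_map, "medium"))

  universe <- if (nrow(targets)) {
    merge(data.frame(substance = scenario$substances), targets, by = NULL)
  } else {
    data.frame(substance = character(0), organ = character(0),
               effect = character(0))
  }
  key <- paste(universe$substance, universe$organ, universe$effect, sep = "\r")
  pkey <- if (nrow(pred_truth)) paste(pred_truth$substance, pred_truth$organ,
                                      pred_truth$effect, sep = "\r")
          else character(0)
  universe$pred <- key %in% pkey

  cc <- scenario$target_concordance
  p_hat <- if (nrow(universe)) mean(universe$pred) else 0
  pi_eff <- if (nrow(universe)) scenario$positive_prevalence else 0
  if (cc > 0 && p_hat > 0) pi_eff <- min(pi_eff, p_hat / cc)
  if (cc < 1 && p_hat < 1) pi_eff <- min(pi_eff, (1 - p_hat) / (1 - cc))
  q1 <- if (p_hat > 0) cc * pi_eff / p_hat else 0
  q0 <- if (p_hat < 1) (1 - cc) * pi_eff / (1 - p_hat) else 0
  with_seed(scenario$seed + 6000L, {
    universe$observed <- runif(nrow(universe)) <
      ifelse(universe$pred, q1, q0)
  })
  in_vivo <- universe[universe$observed, c("substance", "organ", "effect")]
  rownames(in_vivo) <- NULL
  class(in_vivo) <- c("in_vivo_profile", "data.frame")

  bundle <- list(
    scenario = scenario,
    ct = if (include_ct) list(liver = simulate_ct_table(scenario, "liver"),
                              kidney = simulate_ct_table(scenario, "kidney"))
         else NULL,
    protein_panel = simulate_protein_panel(scenario),
    annotations = simulate_annotation_exports(scenario, category_map),
    viability = simulate_viability(scenario),
    in_vivo = in_vivo,
    truth = list(protein = tev$protein, category = tev$category,
                 prediction_set = pred_truth, universe = universe,
                 n_evaluable = nrow(universe), n_pos = sum(universe$observed),
                 target_concordance = cc, q1 = q1, q0 = q0))
  bundle
}

#' Simulate plate-level viability curves
#'
#' A simple sigmoidal concentration response per substance, cell line and
#' assay with Gaussian readout noise, on the percent-of-control scale.
#'
#' @param scenario [simulation_scenario()].
#' @return data.frame: `substance`, `cell_line`, `assay`, `concentration`,
#'   `viability`.
#' @export
simulate_viability <- function(scenario) {
  concs <- c(3, 10, 30, 100, 300, 1000)
  with_seed(scenario$seed + 7000L, {
    grid <- expand.grid(substance = scenario$substances,
                        cell_line = names(scenario$cell_lines),
                        assay = c("WST1", "NR"), stringsAsFactors = FALSE)
    ec50 <- setNames(10^runif(scenario$n_substances, 2, 3.2),
                     scenario$substances)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      v <- 100 / (1 + (concs / ec50[grid$substance[i]])^2) +
        rnorm(length(concs), 0, 2)
      data.frame(grid[i, ], concentration = concs,
                 viability = pmax(v, 0), row.names = NULL)
    })
    do.call(rbind, rows)
  })
}
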