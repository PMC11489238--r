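test_that("simulation is deterministic in the seed and sensitive to it", {
  sc <- simulation_scenario(n_substances = 2,
                            n_target_genes = c(liver = 15, kidney = 8),
                            seed = 9)
  expect_identical(simulate_ct_table(sc, "liver"), simulate_ct_table(sc, "liver"))
  b1 <- simulate_study(sc, include_ct = FALSE)
  b2 <- simulate_study(sc, include_ct = FALSE)
  expect_identical(b1$protein_panel, b2$protein_panel)
  expect_identical(b1$in_vivo, b2$in_vivo)

  sc2 <- simulation_scenario(n_substances = 2,
                             n_target_genes = c(liver = 15, kidney = 8),
                             seed = 10)
  expect_false(identical(simulate_ct_table(sc2, "liver")$ct,
                         simulate_ct_table(sc, "liver")$ct))
})

test_that("vanishing Ct noise recovers the true fold changes", {
  sc <- simulation_scenario(n_substances = 2,
                            n_target_genes = c(liver = 30, kidney = 8),
                            replicate_sd = 1e-6, frac_active_genes = 0.3,
                            seed = 13)
  ct <- simulate_ct_table(sc, "liver")
  lfc <- attr(ct, "true_log2fc")
  expr <- quantify_expression(ct)
  got <- log2(expr$fold_change)
  want <- lfc[cbind(expr$substance, expr$gene)]
  expect_equal(got, unname(want), tolerance = 1e-4)
})

test_that("without true effects essentially no gene passes the DEG gate", {
  sc <- simulation_scenario(n_substances = 1,
                            n_target_genes = c(liver = 500, kidney = 8),
                            frac_active_genes = 0, seed = 17)
  expr <- quantify_expression(simulate_ct_table(sc, "liver"))
  deg <- call_deg(expr)  # needs |FR| >= 2, i.e. |ddCt| >= 1 at sd 0.25
  expect_lt(length(deg) / nrow(expr), 0.01)
})

test_that("protein noise level trades off bootstrap detection power", {
  n_flagged <- sapply(c(0.1, 0.6), function(cv) {
    sc <- simulation_scenario(n_substances = 3, protein_cv = cv,
                              frac_active_markers = 0.5, seed = 23)
    ev <- marker_evidence(simulate_protein_panel(sc), tox_config(n_boot = 1000))
    conds <- attr(ev, "conditions")
    truth <- attr(simulate_protein_panel(sc), "truth")
    key <- paste(conds$substance, conds$cell_line, conds$marker)
    act <- truth$active[match(key, paste(truth$substance, truth$cell_line,
                                         truth$marker))]
    sum(conds$boot_p[act] < 0.05, na.rm = TRUE)
  })
  expect_gt(n_flagged[1], n_flagged[2])
})

test_that("a perfect-information scenario reaches full concordance and agreement", {
  sc <- simulation_scenario(n_substances = 3, protein_cv = 1e-4,
                            target_concordance = 1, positive_prevalence = 1,
                            seed = 29)
  b <- simulate_study(sc, include_ct = FALSE)
  pe <- marker_evidence(b$protein_panel, bootstrap = FALSE)
  te <- category_evidence(b$annotations)
  sw <- threshold_sweep(pe, te, b$in_vivo)
  cc <- sw[sw$scope == "combined:combined" & sw$threshold == "medium", ]
  expect_equal(cc$indicative_concordance, 100)
  expect_equal(cc$negative_agreement, 100)
})

test_that("the in vivo draw hits the requested prevalence and concordance geometry", {
  sc <- simulation_scenario(seed = 31)
  b <- simulate_study(sc, include_ct = FALSE)
  u <- b$truth$universe
  expect_equal(nrow(u), b$truth$n_evaluable)
  expect_gte(b$truth$n_evaluable, 40)
  expect_true(b$truth$q1 >= 0 && b$truth$q1 <= 1)
  expect_true(b$truth$q0 >= 0 && b$truth$q0 <= 1)
  # conditional structure: the share of observed positives that are
  # ground-truth predicted estimates the target concordance
  est <- mean(u$pred[u$observed])
  se <- sqrt(0.75 * 0.25 / sum(u$observed))
  expect_lt(abs(est - sc$target_concordance), 4 * se)
})

test_that("an emptied mapping propagates as a null report with a warning", {
  pm <- load_ontology("protein_map")
  empty <- pm[is.na(pm$effect), ]
  class(empty) <- class(pm)
  sc <- simulation_scenario(n_substances = 2, seed = 37)
  b <- simulate_study(sc, protein_map = empty, category_map = empty,
                      include_ct = FALSE)
  expect_equal(b$truth$n_evaluable, 0)
  pe <- marker_evidence(b$protein_panel, bootstrap = FALSE)
  expect_warning(rep <- compute_concordance(
    map_predictions(pe, empty, "medium"), b$in_vivo, empty),
    "empty evaluation universe")
  expect_true(is.na(rep$indicative_concordance))
})
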