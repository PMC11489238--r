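pm <- load_ontology("protein_map")
cm <- load_ontology("category_map")

test_that("graded endpoints map onto their curated effect categories", {
  ev <- data.frame(substance = "S", cellular_function = "Translation",
                   grade = "strong")
  pred <- map_predictions(ev, pm, "medium", "liver")
  expect_setequal(pred$effect,
                  c("Neoplasms", "Foci of cellular alteration in the liver",
                    "Hypertrophy"))
  expect_true(all(pred$grade == "strong"))

  # an endpoint with no in vivo counterpart predicts nothing
  hyp <- data.frame(substance = "S", cellular_function = "Hypoxia",
                    grade = "very_strong")
  expect_equal(nrow(map_predictions(hyp, pm, "medium")), 0)

  # below threshold contributes nothing
  med <- data.frame(substance = "S", input_scope = "combined",
                    category = "Liver Steatosis", grade = "medium")
  expect_equal(nrow(map_predictions(med, cm, "strong")), 0)
})

test_that("combination endpoints fire only when all members pass", {
  both <- data.frame(substance = "S",
                     category = c("Liver Cholestasis",
                                  "Liver Inflammation/Hepatitis"),
                     grade = c("very_strong", "medium"))
  pred <- map_predictions(both, cm, "medium")
  combo <- pred[grepl("Liver Cholestasis, Liver", pred$endpoints), ]
  expect_true("Inflammation in the liver" %in% pred$effect)
  # the combination contributes its weakest member grade
  expect_true(all(pred$grade[pred$effect == "Inflammation in the liver"] == "medium"))

  one <- both[1, ]
  pred1 <- map_predictions(one, cm, "medium")
  expect_setequal(pred1$effect, "Cholestasis")  # single-category row still fires
  expect_false("Inflammation in the liver" %in% pred1$effect)
})

test_that("OR-combining scopes is a union with the strongest grade", {
  a <- map_predictions(data.frame(substance = "S",
                                  cellular_function = "Apoptosis",
                                  grade = "medium"), pm, "medium", "liver")
  b <- map_predictions(data.frame(substance = "S",
                                  cellular_function = "Autophagy",
                                  grade = "very_strong"), pm, "medium", "liver")
  u <- combine_scopes(a, b)
  expect_equal(nrow(u), 1)  # both predict the same degeneration effect
  expect_equal(u$grade, "very_strong")
  expect_match(u$endpoints, "Apoptosis")
  expect_match(u$endpoints, "Autophagy")
  expect_equal(combine_scopes(a, a)$grade, a$grade)
  expect_equal(nrow(combine_scopes(a[0, ], b[0, ])), 0)
})

test_that("concordance counts observed-positive hits and correct negatives", {
  observed <- data.frame(substance = "S",
                         organ = "liver",
                         effect = c("Neoplasms", "Hypertrophy",
                                    "Oxidative stress"))
  pred <- data.frame(substance = "S", organ = "liver",
                     effect = c("Neoplasms", "Hypertrophy"),
                     grade = "strong", endpoints = "Translation")
  rep <- compute_concordance(pred, observed, pm, organs = "liver")
  expect_equal(rep$n_pos, 3)
  expect_equal(rep$n_hit, 2)
  expect_equal(rep$indicative_concordance, 200 / 3, tolerance = 1e-9)

  none <- pred[0, ]
  rep0 <- compute_concordance(none, observed, pm, organs = "liver")
  expect_equal(rep0$indicative_concordance, 0)
  expect_equal(rep0$negative_agreement, 100)
})

test_that("effects without a mapped predictor leave the denominator unless asked", {
  observed <- data.frame(substance = "S", organ = "liver",
                         effect = c("Neoplasms", "Cholestasis"))
  pred <- data.frame(substance = "S", organ = "liver", effect = "Neoplasms",
                     grade = "strong", endpoints = "Translation")
  # Cholestasis has no protein predictor: excluded by default
  rep <- compute_concordance(pred, observed, pm, organs = "liver")
  expect_equal(rep$n_pos, 1)
  expect_equal(rep$indicative_concordance, 100)
  # ... and scored as an automatic miss when included
  rep2 <- compute_concordance(pred, observed, pm, organs = "liver",
                              include_unmapped = TRUE)
  expect_equal(rep2$n_pos, 2)
  expect_equal(rep2$indicative_concordance, 50)
})

test_that("an empty evaluation universe yields a null report with a warning", {
  empty_map <- pm[is.na(pm$effect), ]
  class(empty_map) <- class(pm)
  observed <- data.frame(substance = "S", organ = "liver",
                         effect = "Neoplasms")
  expect_warning(rep <- compute_concordance(
    data.frame(substance = character(0), organ = character(0),
               effect = character(0), grade = character(0),
               endpoints = character(0)),
    observed, empty_map), "empty evaluation universe")
  expect_true(is.na(rep$indicative_concordance))
  expect_equal(nrow(rep$audit), 0)
})

test_that("the threshold sweep produces the full 7 x 3 design with conserved totals", {
  sc <- simulation_scenario(n_substances = 4, seed = 21)
  b <- simulate_study(sc, include_ct = FALSE)
  pe <- marker_evidence(b$protein_panel, bootstrap = FALSE)
  te <- category_evidence(b$annotations)
  sw <- threshold_sweep(pe, te, b$in_vivo)
  expect_equal(nrow(sw), 21)
  expect_setequal(unique(sw$scope),
                  c("protein:HepaRG", "protein:RPTEC", "protein:combined",
                    "mRNA:HepaRG", "mRNA:RPTEC", "mRNA:combined",
                    "combined:combined"))
  # universe conserved across thresholds within each scope
  tot <- sw$n_pos + sw$n_neg
  expect_true(all(tapply(tot, sw$scope, function(v) length(unique(v))) == 1))
  # stricter thresholds never increase concordance, never decrease
  # negative agreement
  for (scp in unique(sw$scope)) {
    sub <- sw[sw$scope == scp, ]
    sub <- sub[match(c("medium", "strong", "very_strong"), sub$threshold), ]
    expect_true(all(diff(sub$indicative_concordance) <= 1e-9))
    expect_true(all(diff(sub$negative_agreement) >= -1e-9))
  }
})

test_that("all-none evidence and empty substance registries degrade gracefully", {
  sc <- simulation_scenario(n_substances = 2, frac_active_markers = 0,
                            frac_active_categories = 0, protein_cv = 1e-4,
                            seed = 5)
  b <- simulate_study(sc, include_ct = FALSE)
  pe <- marker_evidence(b$protein_panel, bootstrap = FALSE)
  te <- category_evidence(b$annotations)
  sw <- threshold_sweep(pe, te, b$in_vivo)
  expect_true(all(sw$n_hit == 0))
  expect_true(all(sw$n_correct_neg == sw$n_neg))

  no_obs <- b$in_vivo[0, ]
  sw0 <- threshold_sweep(pe, te, no_obs)
  expect_equal(nrow(sw0), 21)
  expect_true(all(sw0$n_pos + sw0$n_neg == 0))
})
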