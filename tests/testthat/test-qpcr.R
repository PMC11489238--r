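test_that("Ct censoring replaces late and undetected wells by the cutoff", {
  out <- censor_ct(c(28.4, 37.1, NA), 35)
  expect_equal(as.numeric(out), c(28.4, 35, 35))
  expect_equal(attr(out, "censored"), c(FALSE, TRUE, TRUE))
  expect_equal(as.numeric(censor_ct(35, 35)), 35)
  expect_false(attr(censor_ct(35, 35), "censored"))
})

test_that("delta-Ct normalizes to the housekeeping mean and names missing references", {
  s <- data.frame(gene = c("g", paste0("HK", 1:5)), ct = c(25, rep(20, 5)))
  expect_equal(unname(delta_ct(s, paste0("HK", 1:5))["g"]), 5)
  s2 <- data.frame(gene = c("g", "HK1"), ct = c(20, 20))
  expect_equal(unname(delta_ct(s2, "HK1")["g"]), 0)
  err <- tryCatch(delta_ct(s2, c("HK1", "HK9"), "sampleA"), error = identity)
  expect_s3_class(err, "toxconcord_normalization_error")
  expect_match(conditionMessage(err), "HK9")
  expect_match(conditionMessage(err), "sampleA")
})

test_that("delta-delta-Ct closed forms hold exactly", {
  r <- ddct_expression(c(4, 4, 4), c(5, 5, 5))
  expect_equal(r$mean_ddct, -1)
  expect_equal(r$fold_change, 2)

  same <- ddct_expression(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$fold_change, 1)

  down <- ddct_expression(c(7, 7, 7), c(5, 5, 5))
  expect_equal(down$fold_change, 0.25)
  expect_equal(down$fold_regulation, -4)

  expect_error(ddct_expression(numeric(0), c(1, 2)),
               class = "toxconcord_missing_data_error")
  # single replicates: fold change yes, p-value no
  single <- ddct_expression(4, 5)
  expect_equal(single$fold_change, 2)
  expect_true(is.na(single$p_value))
})

test_that("fold regulation is the signed fold change and log-antisymmetric", {
  expect_equal(fold_regulation(c(2, 0.5, 1)), c(2, -2, 1))
  expect_error(fold_regulation(0), class = "toxconcord_domain_error")
  set.seed(1)
  x <- exp(runif(50, 0.01, 4))
  expect_equal(fold_regulation(x), -fold_regulation(1 / x))
})

test_that("the cross-platform QC range check compares fold ratios", {
  expect_true(qc_range_check(2.0, 2.0, 3))
  expect_false(qc_range_check(8.0, 1.1, 3))
  expect_true(qc_range_check(0.5, 1.2, 3))  # direction-free
  expect_error(qc_range_check(0, 1, 3), class = "toxconcord_domain_error")
})

test_that("quantify_expression recovers the built-in fold change of a tiny table", {
  expr <- quantify_expression(as_ct_table(tiny_ct_df()))
  tg1 <- expr[expr$gene == "TG1", ]
  expect_equal(tg1$fold_change, 2, tolerance = 1e-9)  # exact 1-cycle shift
  tg2 <- expr[expr$gene == "TG2", ]
  expect_equal(tg2$fold_change, 1, tolerance = 1e-9)
  expect_equal(tg2$p_value, 1)   # zero paired differences
})

test_that("a condition quantified against itself yields fold change 1 everywhere", {
  df <- tiny_ct_df()
  treated <- df[df$group == "untreated_control", ]
  treated$group <- "treated"; treated$substance <- "X"
  treated$sample_id <- paste0(treated$sample_id, "_t")
  expr <- quantify_expression(as_ct_table(rbind(df[df$group != "treated", ],
                                                treated)))
  expect_true(all(abs(expr$fold_change - 1) < 1e-12))
})

test_that("genes censored in every replicate are neutralized and excluded from DEG", {
  df <- tiny_ct_df()
  df$ct[df$gene == "TG1"] <- c(rep(44, 3), rep(39, 3))  # all above cutoff
  expr <- quantify_expression(as_ct_table(df))
  tg1 <- expr[expr$gene == "TG1", ]
  expect_true(tg1$censored_all)
  expect_equal(tg1$fold_change, 1)
  expect_false("TG1" %in% call_deg(expr, fc_threshold = 1.0001, alpha = 1))
})

test_that("quantification errors name the missing pieces", {
  df <- tiny_ct_df()
  df$is_housekeeping <- FALSE
  expect_error(quantify_expression(as_ct_table(df)),
               class = "toxconcord_normalization_error")
  df2 <- tiny_ct_df()[tiny_ct_df()$group == "treated", ]
  expect_error(quantify_expression(as_ct_table(df2)),
               class = "toxconcord_missing_data_error")
})
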