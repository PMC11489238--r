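test_that("bootstrap test handles the no-displacement and clear-effect cases", {
  expect_equal(bootstrap_test(c(100, 100, 100), seed = 1), 1)
  p <- bootstrap_test(c(300, 310, 290), n_boot = 10000, seed = 1)
  expect_lt(p, 0.05)
  # independent loop implementation agrees on the decision
  set.seed(99)
  expect_lt(boot_p_oracle(c(300, 310, 290)), 0.05)
})

test_that("bootstrap p is reproducible, order-invariant, and matches boot::boot", {
  skip_if_not_installed("boot")
  x <- c(160, 80, 130)
  p1 <- bootstrap_test(x, n_boot = 20000, seed = 7)
  expect_identical(p1, bootstrap_test(x, n_boot = 20000, seed = 7))
  expect_identical(p1, bootstrap_test(rev(x), n_boot = 20000, seed = 7))

  # cross-check against the classic resampling package (independent RNG
  # stream, so agreement is statistical, not bitwise)
  set.seed(11)
  bt <- boot::boot(sort(x), function(d, i) mean(d[i]), R = 20000)
  m <- mean(x)
  p_boot <- min(1, 2 * mean(if (m > 100) bt$t <= 100 else bt$t >= 100))
  expect_equal(p1, p_boot, tolerance = 0.02)
})

test_that("bootstrap test enforces its preconditions", {
  expect_error(bootstrap_test(c(100, 120)), class = "toxconcord_missing_data_error")
  expect_error(bootstrap_test(c(100, 120, 130), n_boot = 10),
               class = "toxconcord_config_error")
})

test_that("the protein evidence matrix reproduces its defining cases", {
  expect_equal(as.character(grade_protein(c(247, 120, 110, 95))), "strong")
  expect_equal(as.character(grade_protein(c(210, 230, 160, 140))), "very_strong")
  expect_equal(as.character(grade_protein(c(140, 145, 130, 100))), "none")
  expect_equal(as.character(grade_protein(c(160, 170, 120, 100))), "strong")
  expect_equal(as.character(grade_protein(c(160, 120, 110, 100))), "medium")
  # band boundaries: 150 belongs below the medium band, 200 inside it
  expect_equal(as.character(grade_protein(c(150, 150))), "none")
  expect_equal(as.character(grade_protein(c(150.5, 100))), "medium")
  expect_equal(as.character(grade_protein(c(200, 200))), "strong")
  expect_equal(as.character(grade_protein(c(200.5, 100))), "strong")
  # decreases never contribute
  expect_equal(as.character(grade_protein(c(40, 20, 10, 5))), "none")
})

test_that("protein grading is monotone in every condition mean", {
  set.seed(5)
  for (i in 1:100) {
    means <- runif(4, 80, 260)
    g0 <- grade_protein(means)
    j <- sample(4, 1)
    means[j] <- means[j] + runif(1, 0, 80)
    expect_gte(as.integer(grade_protein(means)), as.integer(g0))
  }
})

test_that("marker evidence summarizes a panel per condition and grades it", {
  sc <- simulation_scenario(n_substances = 2, protein_cv = 1e-4, seed = 3)
  panel <- simulate_protein_panel(sc)
  ev <- marker_evidence(panel, tox_config(n_boot = 1000))
  truth <- attr(panel, "truth")
  m <- merge(as.data.frame(ev), truth,
             by = c("substance", "cell_line", "marker"))
  # in the noise-free limit every active marker grades very_strong
  expect_true(all(m$grade[m$active] == "very_strong"))
  expect_true(all(m$grade[!m$active] == "none"))
  conds <- attr(ev, "conditions")
  expect_equal(nrow(conds), nrow(ev) * 4)
  expect_true(all(conds$boot_p[conds$value > 200] < 0.05))
})

test_that("combining cell lines is a commutative, associative, idempotent max", {
  a <- random_marker_evidence(c("S1", "S2"), seed = 1)
  a$cell_line <- "L1"; a$marker <- a$cellular_function
  a$n_conditions <- 4; a$max_condition_mean <- 100; a$min_boot_p <- NA
  b <- a; b$cell_line <- "L2"
  b$grade <- sample(grade_levels(), nrow(b), replace = TRUE)
  cc <- a; cc$cell_line <- "L3"
  cc$grade <- sample(grade_levels(), nrow(cc), replace = TRUE)

  ab <- combine_cell_lines(a, b)
  ba <- combine_cell_lines(b, a)
  expect_equal(ab$grade, ba$grade)
  expect_equal(combine_cell_lines(ab, cc)$grade,
               combine_cell_lines(a, combine_cell_lines(b, cc))$grade)
  expect_equal(combine_cell_lines(a, a)$grade,
               combine_cell_lines(a)$grade)
  # element-wise: max of the contributing grades
  key <- paste(ab$substance, ab$cellular_function)
  ka <- paste(a$substance, a$cellular_function)
  expect_equal(evidence_grade(ab$grade),
               grade_max(a$grade[match(key, ka)], b$grade[match(key, ka)]))
})
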