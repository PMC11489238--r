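# Programmatic fixtures: every table is built in code at test time.

# A minimal two-gene Ct table: one treated group (3 replicates) vs one
# untreated control group (3 replicates) with an exact 1-cycle shift on TG1
# (fold change 2) and no shift on TG2.
tiny_ct_df <- function() {
  hk <- c("HK1", "HK2")
  mk_sample <- function(id, group, substance, tg1, tg2) {
    data.frame(sample_id = id, cell_line = "HepaRG", substance = substance,
               concentration = if (group == "treated") 100 else 0, time = 36,
               group = group,
               gene = c("TG1", "TG2", hk),
               ct = c(tg1, tg2, 20, 20),
               is_housekeeping = c(FALSE, FALSE, TRUE, TRUE))
  }
  rbind(
    mk_sample("c1", "untreated_control", "none", 25.0, 26.0),
    mk_sample("c2", "untreated_control", "none", 25.2, 26.1),
    mk_sample("c3", "untreated_control", "none", 24.8, 25.9),
    mk_sample("t1", "treated", "X", 24.0, 26.0),
    mk_sample("t2", "treated", "X", 24.2, 26.1),
    mk_sample("t3", "treated", "X", 23.8, 25.9))
}

write_tmp_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr_tempdir(), name)
  write.csv(df, path, row.names = FALSE)
  path
}

# tempdir helper without extra deps
withr_tempdir <- local({
  d <- NULL
  function() {
    if (is.null(d)) {
      d <<- file.path(tempdir(), "toxconcord-tests")
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
    }
    d
  }
})

# Random marker-evidence table over a fixed endpoint set.
random_marker_evidence <- function(substances, seed) {
  funs <- protein_marker_functions()$cellular_function
  g <- expand.grid(substance = substances, cellular_function = funs,
                   stringsAsFactors = FALSE)
  set.seed(seed)
  g$grade <- sample(grade_levels(), nrow(g), replace = TRUE)
  g
}
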