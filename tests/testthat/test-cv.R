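test_that("fold plans partition the rows and stay fixed across levels", {
  plan <- cv_plan(31, K = 3, R = 4, seed = 2)
  expect_identical(dim(plan$folds), c(31L, 4L))
  for (r in 1:4) {
    counts <- tabulate(plan$folds[, r], nbins = 3)
    expect_true(all(abs(counts - 31 / 3) <= 1)) # n/3 +- 1 per fold
    expect_identical(sum(counts), 31L)          # every row tested once
  }
  expect_identical(cv_plan(31, K = 3, R = 4, seed = 2), plan)

  strat <- cv_plan(30, K = 3, R = 2, seed = 3, y = rep(0:1, each = 15), stratify = TRUE)
  for (r in 1:2) {
    for (cl in 0:1) {
      idx <- rep(0:1, each = 15) == cl
      expect_true(all(tabulate(strat$folds[idx, r], 3) == 5))
    }
  }
  expect_error(cv_plan(2, K = 3), "n >= K")
})

test_that("the harness scores every method cell and aggregates are recomputable", {
  tab <- balanced_table(48, seed = 40)
  spec <- missingness_spec("mcar", levels = c(0.1, 0.2), seed = 4)
  pats <- generate_patterns(tab, spec, replicates = 2)
  plan <- cv_plan(48, K = 3, R = 2, seed = 5)
  rep1 <- run_repeated_cv(
    tab, pats, methods = c("CF", "LR-MI"), plan = plan,
    cf = cf_config(k_grid = c(3, 5)), opts = cv_options(ntree = 50)
  )
  rec <- rep1$records
  expect_identical(nrow(rec), 2L * 2L * 3L * 2L) # methods x levels x folds x reps
  expect_true(all(!rec$failed))
  expect_true(all(rec$misclass >= 0 & rec$misclass <= 1))
  expect_true(all(is.na(rec$brier[rec$method == "CF"])))
  expect_true(all(rec$brier[rec$method == "LR-MI"] >= 0))

  # aggregates recomputable from records to 1e-12
  agg <- rep1$aggregates
  for (i in seq_len(nrow(agg))) {
    sel <- rec$method == agg$method[i] & rec$level == agg$level[i]
    expect_lt(abs(mean(rec$misclass[sel]) - agg$mean_misclass[i]), 1e-12)
    expect_lt(abs(sd(rec$misclass[sel]) - agg$spread_misclass[i]), 1e-12)
  }

  # bit-identical rerun under the same plan and patterns
  rep2 <- run_repeated_cv(
    tab, pats, methods = c("CF", "LR-MI"), plan = plan,
    cf = cf_config(k_grid = c(3, 5)), opts = cv_options(ntree = 50)
  )
  expect_identical(rep1, rep2)
})

test_that("a majority-class predictor scores near the minority rate", {
  tab <- generate_dataset(sim_config(n = 150, minority_rate = 0.3, seed = 41))
  plan <- cv_plan(150, K = 3, R = 1, seed = 6)
  folds <- plan$folds[, 1]
  errs <- vapply(1:3, function(f) {
    tr <- table_rows(tab, folds != f)
    te <- table_rows(tab, folds == f)
    maj <- names(which.max(table(tr$y)))
    misclassification(te$y, rep(maj, nrow(te$x)))
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.3), 0.1)
})

test_that("report summaries mirror the records and survive a disk round-trip", {
  tab <- balanced_table(36, seed = 42)
  pats <- generate_patterns(tab, missingness_spec("mcar", levels = 0.1, seed = 7), 1)
  plan <- cv_plan(36, K = 3, R = 1, seed = 8)
  rep1 <- run_repeated_cv(tab, pats, methods = "LR-MI", plan = plan,
                          opts = cv_options(ntree = 50))
  dir <- withr::local_tempdir()
  paths <- write_report(rep1, dir)
  summ <- summarize_report(unname(paths["records"]))
  expect_equal(summ$aggregates$mean_misclass, rep1$aggregates$mean_misclass)
  expect_true(all(c("metric", "value") %in% names(summ$long)))

  # single record: mean equals the record, spread zero
  one <- rep1$records[1, , drop = FALSE]
  agg1 <- summarize_report(structure(
    list(records = one), class = "cv_report"
  ))$aggregates
  expect_equal(agg1$mean_misclass, one$misclass)
  expect_equal(agg1$spread_misclass, 0)

  # two folds 0.2 / 0.4 aggregate to mean 0.3 and spread sd(c(.2,.4))
  two <- rbind(one, one)
  two$fold <- c(1, 2)
  two$misclass <- c(0.2, 0.4)
  agg2 <- summarize_report(structure(list(records = two), class = "cv_report"))$aggregates
  expect_equal(agg2$mean_misclass, 0.3)
  expect_equal(agg2$spread_misclass, sd(c(0.2, 0.4)))

  expect_error(summarize_report(file.path(dir, "nope.csv")), "not found")
})
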