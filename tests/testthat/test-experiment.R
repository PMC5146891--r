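test_that("labeled tables round-trip through CSV plus schema sidecar", {
  tab <- balanced_table(25, seed = 50)
  masked <- apply_mask(tab, inject_mcar(tab, 0.2, seed = 51))
  dir <- withr::local_tempdir()
  data_path <- file.path(dir, "t.csv")
  schema_path <- file.path(dir, "t.json")
  write_labeled_table(masked, data_path, schema_path)

  # the NA token appears in the file and comes back as a missing marker
  expect_true(any(grepl(",NA", readLines(data_path), fixed = TRUE)))
  back <- load_table(data_path, schema_path)
  expect_equal(back$x, masked$x, tolerance = 1e-12)
  expect_identical(as.character(back$y), as.character(masked$y))
  expect_identical(
    vapply(names(back$x), function(nm) back$schema[[nm]]$kind, ""),
    vapply(names(masked$x), function(nm) masked$schema[[nm]]$kind, "")
  )
})

test_that("declared exclusion codes drop whole rows at load time", {
  dir <- withr::local_tempdir()
  df <- data.frame(X1 = c(1, 2, 999, 4, 5, 6, 999, 8, 9, 10), X2 = 1:10, Y = rep(0:1, 5))
  write.csv(df, file.path(dir, "d.csv"), row.names = FALSE, quote = FALSE)
  side <- list(
    X1 = list(kind = "continuous", exclude = 999),
    X2 = list(kind = "continuous"),
    Y = list(kind = "categorical", levels = c(0, 1), response = TRUE)
  )
  jsonlite::write_json(side, file.path(dir, "d.json"), auto_unbox = TRUE)
  tab <- load_table(file.path(dir, "d.csv"), file.path(dir, "d.json"))
  expect_identical(nrow(tab$x), 8L)
  expect_false(any(tab$x$X1 == 999))

  # schema gaps and absent response are hard errors
  bad <- side
  bad$X2 <- NULL
  jsonlite::write_json(bad, file.path(dir, "bad.json"), auto_unbox = TRUE)
  expect_error(load_table(file.path(dir, "d.csv"), file.path(dir, "bad.json")), "X2")
})

test_that("run_experiment orchestrates the six-step pipeline deterministically", {
  cfg <- experiment_config(
    data = sim_config(n = 60, seed = 60),
    mechanisms = c("mcar", "mar"),
    levels = 0.1,
    methods = c("CF", "LR-MI"),
    K = 3, R = 1,
    cf = cf_config(k_grid = c(3, 5)),
    opts = cv_options(ntree = 50),
    seed = 9
  )
  rep1 <- run_experiment(cfg)
  # 2 methods x 3 folds per mechanism
  expect_identical(nrow(rep1$records), 12L)
  expect_setequal(unique(rep1$records$mechanism), c("mcar", "mar"))

  rep2 <- run_experiment(cfg)
  expect_identical(rep1, rep2)
})

test_that("run_experiment writes records, summary and manifest without touching inputs", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "in")
  dir.create(data_dir)
  tab <- balanced_table(45, seed = 61)
  write_labeled_table(tab, file.path(data_dir, "d.csv"), file.path(data_dir, "d.json"))
  before <- tools::md5sum(list.files(data_dir, full.names = TRUE))

  cfg <- experiment_config(
    data = list(data = file.path(data_dir, "d.csv"), schema = file.path(data_dir, "d.json")),
    mechanisms = "mcar", levels = 0.1, methods = "RF-MI",
    K = 3, R = 1, opts = cv_options(ntree = 50),
    out_dir = file.path(dir, "out"), seed = 10
  )
  rep1 <- run_experiment(cfg)
  expect_true(file.exists(file.path(dir, "out", "cv_records.csv")))
  expect_true(file.exists(file.path(dir, "out", "cv_summary.json")))
  manifest <- jsonlite::read_json(file.path(dir, "out", "manifest.json"))
  expect_equal(manifest$seed, 10)
  expect_identical(tools::md5sum(list.files(data_dir, full.names = TRUE)), before)

  summ <- summarize_report(file.path(dir, "out", "cv_records.csv"))
  expect_equal(summ$aggregates$mean_misclass, rep1$aggregates$mean_misclass)
})
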