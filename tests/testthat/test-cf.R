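test_that("patient similarity is the cosine over co-observed items", {
  u <- c(1, 2, NA, 4)
  expect_equal(patient_similarity(u, u), 1)
  expect_equal(patient_similarity(c(1, 2), c(2, 1)), 0.8)
  expect_true(is.na(patient_similarity(c(1, NA), c(NA, 2))))
  expect_true(is.na(patient_similarity(c(0, 0), c(1, 1))))

  set.seed(3)
  for (i in 1:30) {
    a <- sample(c(1:4, NA), 6, replace = TRUE)
    b <- sample(c(1:4, NA), 6, replace = TRUE)
    expect_identical(patient_similarity(a, b), patient_similarity(b, a))
    s <- patient_similarity(a, b)
    if (!is.na(s)) expect_true(s >= -1 && s <= 1)
  }
})

test_that("cosine similarity is invariant to positive row rescaling", {
  set.seed(11)
  for (i in 1:20) {
    fix <- random_rating_fixture(i)
    rm <- fix$matrix
    resp <- attr(rm, "response_item")
    t_idx <- which(!attr(rm, "train"))[1]
    if (is.na(t_idx)) next
    base <- cosine_to_rows(rm[t_idx, -resp], rm[attr(rm, "train"), -resp, drop = FALSE])
    scaled <- cosine_to_rows(3.7 * rm[t_idx, -resp], rm[attr(rm, "train"), -resp, drop = FALSE])
    expect_equal(base, scaled)
  }
})

test_that("neighbourhoods rank by similarity with lower-id tie-breaks", {
  # rows 2 and 3 duplicate the target; row 4 is orthogonal-ish
  entries <- rbind(
    c(1, 2, 1, NA),
    c(1, 2, 1, 1),
    c(1, 2, 1, 2),
    c(4, 1, 1, 1)
  )
  rm <- structure(
    entries, train = c(FALSE, TRUE, TRUE, TRUE), response_item = 4L,
    class_levels = c("0", "1"), level_count = c(4L, 4L, 4L, 2L),
    class = c("rating_matrix", "matrix", "array")
  )
  nbh <- find_neighborhood(1, rm, k = 2)
  expect_identical(nbh$ids, c(2L, 3L)) # both sim 1; ties to lower id
  expect_equal(nbh$sims, c(1, 1))

  all_of_them <- find_neighborhood(1, rm, k = 10)
  expect_identical(length(all_of_them$ids), 3L) # saturation: every candidate

  top1 <- find_neighborhood(1, rm, k = 1)
  expect_identical(top1$ids, 2L)
  expect_equal(top1$sims, 1)
})

test_that("item prediction follows the renormalized weighted mean and fallbacks", {
  entries <- rbind(
    c(2, NA, NA),
    c(2, 2, 1),
    c(2, 4, 1),
    c(2, 3, 2)
  )
  rm <- structure(
    entries, train = c(FALSE, TRUE, TRUE, TRUE), response_item = 3L,
    class_levels = c("0", "1"), level_count = c(4L, 4L, 2L),
    class = c("rating_matrix", "matrix", "array")
  )
  # constant values win regardless of weights
  nbh <- list(ids = c(2L, 3L), sims = c(0.9, 0.2))
  expect_identical(as.integer(predict_item(1, 1, nbh, rm)), 2L)

  # weighted mean 10/3 rounds half-up to level 3
  nbh <- list(ids = c(2L, 3L), sims = c(0.5, 1.0))
  est <- predict_item(1, 2, nbh, rm)
  expect_equal(attr(est, "raw"), 10 / 3)
  expect_identical(as.integer(est), 3L)

  # equal similarities degrade to the plain neighbourhood average
  nbh <- list(ids = c(2L, 3L, 4L), sims = c(0.4, 0.4, 0.4))
  expect_equal(attr(predict_item(1, 2, nbh, rm), "raw"), 3)

  # no neighbour observes the item: global training mean, level-rounded
  nbh <- list(ids = 2L, sims = 1)
  empty_col <- rm
  empty_col[2, 2] <- NA
  expect_identical(as.integer(predict_item(1, 2, list(ids = 2L, sims = 1), empty_col)), 4L)

  # response: weighted mean of 0/1 codes thresholded at 0.5
  nbh <- list(ids = c(2L, 4L), sims = c(0.3, 0.9))
  expect_identical(as.integer(predict_item(1, 3, nbh, rm)), 2L)
  # empty neighbourhood: training majority class (ties -> smallest code)
  expect_identical(predict_item(1, 3, list(ids = integer(0), sims = numeric(0)), rm), 1L)
})

test_that("pre-rounding estimates stay within the contributors' range", {
  for (i in 1:25) {
    fix <- random_rating_fixture(100 + i)
    rm <- fix$matrix
    resp <- attr(rm, "response_item")
    for (t in which(!attr(rm, "train"))) {
      nbh <- find_neighborhood(t, rm, k = fix$k)
      if (!length(nbh$ids)) next
      for (item in seq_len(resp - 1)) {
        vals <- rm[nbh$ids, item]
        vals <- vals[!is.na(vals)]
        if (!length(vals)) next
        raw <- attr(predict_item(t, item, nbh, rm), "raw")
        expect_gte(raw, min(vals) - 1e-12)
        expect_lte(raw, max(vals) + 1e-12)
      }
    }
  }
})

test_that("response prediction matches the naive direct oracle", {
  for (seed in 1:40) {
    fix <- random_rating_fixture(seed)
    got <- predict_response(fix$matrix, cf_config(k = fix$k))
    want <- oracle_cf_predict(fix$entries, fix$train, fix$resp_col, fix$k)
    expect_identical(
      as.integer(got),
      want,
      info = sprintf("fixture seed %d (k=%d)", seed, fix$k)
    )
  }
})

test_that("degenerate matrices fall back instead of failing", {
  fix <- discretized_fixture(18, seed = 4, miss_rate = 0)
  tab <- fix$table
  # constant response: every prediction is that label
  const <- tab
  const$y <- factor(rep("0", nrow(tab$x)), levels = c("0", "1"))
  rm <- rating_matrix(const, fix$train)
  pred <- predict_response(rm, cf_config(k = 3))
  expect_true(all(pred == "0"))

  # test row duplicating a training row recovers its label at k = 1
  dup <- tab
  dup$x[nrow(dup$x), ] <- dup$x[1, ]
  rm2 <- rating_matrix(dup, fix$train)
  pred2 <- predict_response(rm2, cf_config(k = 1))
  expect_identical(as.character(pred2[length(pred2)]), as.character(dup$y[1]))
})

test_that("k selection minimizes inner-CV misclassification with ties to small k", {
  cfg <- cf_config(k_grid = 5)
  fix <- discretized_fixture(24, seed = 6)
  rm <- rating_matrix(fix$table, fix$train)
  expect_identical(select_k(rm, cfg), 5L)

  # three copies each of four well-separated prototypes: the duplicate
  # dominates at k=1 while a near-global neighbourhood mixes the classes
  protos <- rbind(
    c(1, 4, 1, 4), c(4, 1, 4, 1),
    c(1, 3, 1, 3), c(3, 1, 3, 1)
  )
  x <- protos[rep(1:4, each = 3), ]
  y <- factor(rep(c(0, 1, 0, 1), each = 3))
  tab <- labeled_table(
    as.data.frame(x), y,
    schema = c(
      setNames(rep(list(list(kind = "ordinal", levels = 1:4)), 4), paste0("V", 1:4)),
      list(Y = list(kind = "categorical", levels = c("0", "1")))
    )
  )
  names(tab$x) <- paste0("V", 1:4)
  rm2 <- rating_matrix(tab, train = rep(TRUE, 12))
  cfg2 <- cf_config(k_grid = c(1, 7), seed = 2)
  expect_identical(select_k(rm2, cfg2), 1L)
  expect_identical(select_k(rm2, cfg2), select_k(rm2, cfg2))

  expect_error(select_k(rm2, cf_config(k_grid = 50)), "no feasible k")
})
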