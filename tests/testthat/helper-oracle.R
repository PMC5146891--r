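# Independent oracles, written as plain nested loops so they share no code
# path with the package implementation.

# Cosine similarity of two rating vectors over their co-observed items,
# straight from the definition; NA when undefined.
oracle_cosine <- function(u, v) {
  num <- 0
  nu <- 0
  nv <- 0
  any_overlap <- FALSE
  for (i in seq_along(u)) {
    if (!is.na(u[i]) && !is.na(v[i])) {
      any_overlap <- TRUE
      num <- num + u[i] * v[i]
      nu <- nu + u[i]^2
      nv <- nv + v[i]^2
    }
  }
  if (!any_overlap || nu == 0 || nv == 0) return(NA_real_)
  # a cosine is bounded by 1; clamp the accumulated rounding noise so exact
  # ties rank identically regardless of summation order
  min(1, max(-1, num / (sqrt(nu) * sqrt(nv))))
}

# Naive user-based CF response prediction: for each test row, rank training
# rows by cosine similarity over predictor items (ties to the lower row
# id), keep the top k with defined similarity, and predict the response by
# the renormalized similarity-weighted mean of the 0/1 class codes
# (threshold 0.5, exact ties to the training majority, smallest code on
# majority ties), falling back to the unweighted mean at zero total weight
# and to the training majority when no neighbour observes the response.
oracle_cf_predict <- function(entries, train, resp_col, k) {
  n <- nrow(entries)
  test_rows <- which(!train)
  train_rows <- which(train)

  maj <- function() {
    codes <- entries[train_rows, resp_col]
    codes <- codes[!is.na(codes)]
    counts <- c(sum(codes == 1), sum(codes == 2))
    if (counts[1] >= counts[2]) 1L else 2L
  }

  out <- integer(length(test_rows))
  for (ti in seq_along(test_rows)) {
    t <- test_rows[ti]
    sims <- c()
    ids <- c()
    for (h in train_rows) {
      if (h == t) next
      s <- oracle_cosine(entries[t, -resp_col], entries[h, -resp_col])
      if (!is.na(s)) {
        sims <- c(sims, s)
        ids <- c(ids, h)
      }
    }
    if (length(ids)) {
      ord <- order(-sims, ids)
      take <- ord[seq_len(min(k, length(ord)))]
      nb_ids <- ids[take]
      nb_sims <- sims[take]
      vals <- entries[nb_ids, resp_col]
      keep <- !is.na(vals)
      vals <- vals[keep]
      w <- nb_sims[keep]
    } else {
      vals <- numeric(0)
    }
    if (!length(vals)) {
      out[ti] <- maj()
      next
    }
    if (abs(sum(w)) < 1e-12) w <- rep(1, length(vals))
    est <- sum(w * (vals - 1)) / sum(w)
    out[ti] <- if (est > 0.5) 2L else if (est < 0.5) 1L else maj()
  }
  out
}

# Textbook Hosmer-Lemeshow statistic on equal-occupancy groups of sorted
# probabilities (valid for fixtures whose probabilities are distinct and
# divide evenly into the groups).
oracle_hl_statistic <- function(p, y, groups = 10) {
  ord <- order(p)
  p <- p[ord]
  y <- y[ord]
  per <- length(p) / groups
  stat <- 0
  for (g in seq_len(groups)) {
    idx <- ((g - 1) * per + 1):(g * per)
    pibar <- mean(p[idx])
    O <- sum(y[idx])
    E <- per * pibar
    stat <- stat + (O - E)^2 / (per * pibar * (1 - pibar))
  }
  stat
}

# Random small rating matrix with a hidden response for test rows.
random_rating_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(8:20, 1)
  p <- sample(2:5, 1)
  L <- 4L
  entries <- matrix(sample(1:L, n * p, replace = TRUE), nrow = n)
  miss_rate <- stats::runif(1, 0, 0.3)
  entries[matrix(stats::runif(n * p) < miss_rate, nrow = n)] <- NA_integer_
  train <- rep(FALSE, n)
  train[sample(n, max(2, floor(2 * n / 3)))] <- TRUE
  resp <- sample(1:2, n, replace = TRUE)
  resp[!train] <- NA_integer_
  entries <- cbind(entries, resp)
  colnames(entries) <- c(paste0("X", seq_len(p)), "Y")
  rm <- structure(
    entries,
    train = train,
    response_item = p + 1L,
    class_levels = c("0", "1"),
    level_count = c(rep(L, p), 2L),
    class = c("rating_matrix", "matrix", "array")
  )
  list(matrix = rm, entries = entries, train = train, resp_col = p + 1L,
       k = sample(1:5, 1))
}
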