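#' Configuration for the synthetic clinical-table generator
#'
#' The generator draws iid standard-normal predictors, forms a linear latent
#' response `Y = X beta + lambda * eps` with standard-normal noise, and
#' dichotomizes it. With `minority_rate = 0.5` the cut is at the sample mean;
#' smaller rates label the upper tail of the latent response as the minority
#' class, hitting the requested rate exactly.
#'
#' @param n sample count (>= 2).
#' @param p predictor count.
#' @param beta coefficient vector of length `p`. Default `c(1, 1, 0.1, 0.1,
#'   0.1)`: two strong and three weak predictors.
#' @param lambda non-negative noise scale. Default `1e-2`, a nearly
#'   noise-free latent response.
#' @param minority_rate target minority-class fraction in (0, 0.5].
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, p = 5, beta = c(1, 1, 0.1, 0.1, 0.1),
                       lambda = 1e-2, minority_rate = 0.5, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) stopf("invalid config: n must be >= 2")
  if (!is.numeric(p) || length(p) != 1 || p < 1) stopf("invalid config: p must be >= 1")
  if (length(beta) != p) stopf("invalid config: length(beta) = %d but p = %d", length(beta), p)
  if (!is.numeric(lambda) || lambda < 0) stopf("invalid config: lambda must be >= 0")
  if (!is.numeric(minority_rate) || minority_rate <= 0 || minority_rate > 0.5) {
    stopf("invalid config: minority_rate must lie in (0, 0.5]")
  }
  structure(
    list(
      n = as.integer(n), p = as.integer(p), beta = as.numeric(beta),
      lambda = as.numeric(lambda), minority_rate = as.numeric(minority_rate),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw the predictor matrix
#'
#' Predictors are iid N(0, 1); reproducible under the configured seed.
#'
#' @param config a [sim_config()].
#' @return An `n x p` numeric matrix with columns `X1..Xp`.
#' @export
generate_predictors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  X <- with_seed(
    derive_seed(config$seed, 101L),
    matrix(stats::rnorm(config$n * config$p), nrow = config$n, ncol = config$p)
  )
  colnames(X) <- paste0("X", seq_len(config$p))
  X
}

#' Form the latent linear response
#'
#' `Y_i = sum_j X_ij beta_j + lambda * eps_i` with fresh standard-normal
#' noise drawn from its own stream, independent of the predictor draw.
#'
#' @param X predictor matrix.
#' @param beta coefficient vector matching `ncol(X)`.
#' @param lambda non-negative noise scale.
#' @param seed integer seed for the noise stream.
#' @return Numeric vector of length `nrow(X)`.
#' @export
generate_latent_response <- function(X, beta, lambda, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) {
    stopf("dimension mismatch: ncol(X) = %d, length(beta) = %d", ncol(X), length(beta))
  }
  if (lambda < 0) stopf("lambda must be >= 0")
  eps <- with_seed(derive_seed(seed, 202L), stats::rnorm(nrow(X)))
  drop(X %*% beta) + lambda * eps
}

#' Dichotomize a latent response into class labels
#'
#' With `minority_rate = 0.5` the label is 1 iff the value exceeds the sample
#' mean. With `minority_rate < 0.5`, exactly `ceiling(minority_rate * n)` of
#' the largest latent values are labelled 1 (the minority class), i.e. the
#' threshold sits at the corresponding upper order statistic, so the printed
#' imbalance rate is achieved exactly.
#'
#' @param y latent response, no missing values.
#' @param minority_rate minority fraction in (0, 0.5].
#' @return Integer 0/1 vector; 1 is the minority (upper-tail) class.
#' @export
dichotomize_response <- function(y, minority_rate = 0.5) {
  if (anyNA(y)) stopf("latent response contains missing values")
  n <- length(y)
  if (n < 1) stopf("empty response")
  if (max(y) == min(y)) stopf("degenerate response: constant latent values")
  if (minority_rate >= 0.5) {
    labels <- as.integer(y > mean(y))
  } else {
    m <- as.integer(ceiling(minority_rate * n))
    ord <- order(y, decreasing = TRUE)
    labels <- integer(n)
    labels[ord[seq_len(m)]] <- 1L
  }
  labels
}

#' Generate a complete synthetic clinical table
#'
#' Composes [generate_predictors()], [generate_latent_response()] and
#' [dichotomize_response()] into a fully observed [labeled_table()] whose
#' schema marks every predictor continuous.
#'
#' @param config a [sim_config()].
#' @return A `labeled_table` with binary response at the configured
#'   imbalance and no missing cells.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  X <- generate_predictors(config)
  y_latent <- generate_latent_response(X, config$beta, config$lambda, seed = config$seed)
  labels <- dichotomize_response(y_latent, config$minority_rate)
  schema <- c(
    stats::setNames(
      rep(list(list(kind = "continuous", levels = NULL)), config$p),
      colnames(X)
    ),
    list(Y = list(kind = "categorical", levels = c("0", "1")))
  )
  labeled_table(X, factor(labels, levels = c(0, 1)), schema = schema, response_name = "Y")
}
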