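# Small builders shared across tests; all fixtures are generated in code.

toy_table <- function(x, y, kinds = NULL) {
  x <- as.data.frame(x)
  schema <- NULL
  if (!is.null(kinds)) {
    schema <- lapply(seq_along(kinds), function(i) {
      if (kinds[i] == "continuous") {
        list(kind = "continuous", levels = NULL)
      } else {
        list(kind = kinds[i], levels = sort(unique(x[[i]][!is.na(x[[i]])])))
      }
    })
    names(schema) <- names(x)
  }
  labeled_table(x, y, schema = schema)
}

balanced_table <- function(n = 60, seed = 1) {
  generate_dataset(sim_config(n = n, seed = seed))
}

# A discretized table plus train index, ready for rating_matrix().
discretized_fixture <- function(n = 30, seed = 2, miss_rate = 0.1) {
  tab <- balanced_table(n, seed)
  if (miss_rate > 0) {
    mask <- inject_mcar(tab, miss_rate, seed = seed + 1)
    tab <- apply_mask(tab, mask)
  }
  train <- seq_len(n) <= floor(2 * n / 3)
  scheme <- fit_discretization(tab, rows = which(train))
  list(table = discretize_table(tab, scheme), train = which(train))
}
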