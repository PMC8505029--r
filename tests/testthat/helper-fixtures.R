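# Shared fixtures, all generated in code.

# small deterministic dichotomous matrix with clear structure
toy_matrix <- function(n = 40, k = 5, seed = 100) {
  set.seed(seed)
  theta <- rnorm(n)
  delta <- seq(-1, 1, length.out = k)
  Y <- sapply(delta, function(d) rbinom(n, 1, plogis(theta - d)))
  colnames(Y) <- paste0("i", seq_len(k))
  Y
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# calibration tibble built directly from known difficulties
make_calibration <- function(deltas, ses = NULL) {
  rows <- purrr::map_dfr(seq_along(deltas), function(i) {
    st <- deltas[[i]]
    tibble::tibble(item_id = names(deltas)[i], step = seq_along(st), delta = st,
                   se = if (is.null(ses)) 0.1 else ses[[i]])
  })
  rows
}
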