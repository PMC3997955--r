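# Independent oracles and small fixtures shared across the suite.

# Duncan range-scan oracle, by direct existential characterisation: a pair
# (i, j) of descending-sorted means is NOT separated iff some containing
# range (a, b) — including (i, j) itself — has end-point difference within
# its least significant range. Structurally different from the package's
# sequential marking scan.
oracle_duncan_separation <- function(means, lsr_by_span) {
  k <- length(means)
  sep <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      covered <- FALSE
      for (a in seq_len(i)) {
        for (b in j:k) {
          if (means[a] - means[b] <= lsr_by_span[b - a + 1]) covered <- TRUE
        }
      }
      sep[i, j] <- sep[j, i] <- !covered
    }
  }
  sep
}

# letters -> do two groups share at least one letter?
shares_letter <- function(letters_vec) {
  k <- length(letters_vec)
  chars <- lapply(letters_vec, function(s) strsplit(s, "")[[1]])
  out <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- length(intersect(chars[[i]], chars[[j]])) > 0
    }
  }
  out
}

# balanced one-way draw: k groups x n plants around the given means
draw_panel_values <- function(means, n, sd = 1) {
  tibble::tibble(
    group = rep(sprintf("g%02d", seq_along(means)), each = n),
    value = rep(means, each = n) + stats::rnorm(length(means) * n, 0, sd)
  )
}

tiny_config <- function(..., n = 2) {
  tol <- seq(0.2, 0.8, length.out = n)
  names(tol) <- sprintf("C%02d", seq_len(n))
  panel_config(tol, ...)
}
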