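# Build a small named count matrix (samples x ASVs) from a vector.
tbl <- function(..., nrow, sample_ids = NULL, asv_ids = NULL) {
  m <- matrix(c(...), nrow = nrow, byrow = TRUE)
  rownames(m) <- sample_ids %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- asv_ids %||% paste0("A", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# C(n+m, n) group assignments (matches R's exact convention: double the
# smaller tail, capped at 1).
wilcox_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ws <- apply(utils::combn(n + m, n), 2,
              function(idx) sum(r[idx]) - n * (n + 1) / 2)
  if (w_obs > n * m / 2) min(1, 2 * mean(ws >= w_obs))
  else min(1, 2 * mean(ws <= w_obs))
}

# Direct-formula Bray-Curtis for two count vectors.
bray_direct <- function(x, y) sum(abs(x - y)) / sum(x + y)
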