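# Independent reference implementations used to validate the package's fast
# paths. These are deliberately naive: position-by-position scans and
# normal-equations algebra, sharing no code with the package.

# sliding-window motif count, checking every start position
naive_count <- function(sequence, motif) {
  L <- nchar(sequence)
  k <- nchar(motif)
  if (k > L) return(0L)
  hits <- 0L
  for (p in seq_len(L - k + 1L)) {
    if (substr(sequence, p, p + k - 1L) == motif) hits <- hits + 1L
  }
  hits
}

# base frequencies by direct counting
naive_freqs <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  vapply(c(A = "A", C = "C", G = "G", U = "U"),
         function(b) sum(chars == b) / length(chars), numeric(1))
}

# Eq-style OE ratio from the naive parts: obs / (L * prod f)
naive_oe <- function(sequence, motif) {
  f <- naive_freqs(sequence)
  bases <- strsplit(motif, "", fixed = TRUE)[[1]]
  e <- nchar(sequence) * prod(f[bases])
  if (e == 0) 0 else naive_count(sequence, motif) / e
}

# OLS by explicit normal equations (test oracle only; numerically inferior to
# the QR route the package uses, which is the point of the comparison)
normal_equations_ols <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  list(beta = as.vector(beta), r2 = 1 - rss / tss, residuals = res)
}

# random RNA string with given base probabilities
random_rna <- function(L, probs = c(A = .25, C = .25, G = .25, U = .25)) {
  paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
}

# random composition on the simplex (kept away from degenerate corners)
random_composition <- function() {
  p <- rgamma(4, shape = 1) + 0.05
  setNames(p / sum(p), c("A", "C", "G", "U"))
}

# strip class/provenance so value comparisons see only the data
plain <- function(df) {
  out <- as.data.frame(df)
  attributes(out) <- list(names = names(out),
                          row.names = seq_len(nrow(out)),
                          class = "data.frame")
  out
}

# write a small FASTA inline
write_fasta_lines <- function(...) {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(...), path)
  path
}
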