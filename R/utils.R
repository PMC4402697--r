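# internal numeric + misc helpers

# log(exp(a) + exp(b)) without overflow; handles -Inf on either side
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

# locale-independent sort (C collation) so edge keys are reproducible
sort_c <- function(x) sort(x, method = "radix")

# indices of the upper triangle of an n x n matrix, as parallel vectors
upper_pairs <- function(n) {
  if (n < 2L) return(list(i = integer(0), j = integer(0)))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  list(i = idx[ord, 1L], j = idx[ord, 2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
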