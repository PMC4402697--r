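# Independent brute-force oracles, deliberately kept separate from the
# package's own code paths: configurations are enumerated as bit masks
# over all 2^(n(n-1)/2) graphs, transitivity is checked by the triple
# rule, and probabilities are plain products.

pair_index <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# adjacency matrix from a bit mask over the upper triangle
mask_to_adj <- function(mask, n) {
  up <- pair_index(n)
  m <- nrow(up)
  e <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
  adj <- matrix(FALSE, n, n)
  adj[up] <- e
  adj | t(adj)
}

# transitivity by the triple rule: every two-edge path closes
adj_is_transitive <- function(adj) {
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (adj[i, j] && adj[j, k] && !adj[i, k]) return(FALSE)
  }
  TRUE
}

# plain product probability of a configuration mask given pair probs
mask_prob <- function(mask, probs) {
  m <- length(probs)
  e <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
  prod(ifelse(e, probs, 1 - probs))
}

# exact conditionals by exhaustive filtering (feasible for n <= 5)
brute_force_conditionals <- function(probs, n) {
  m <- n * (n - 1) / 2
  stopifnot(length(probs) == m, m <= 15)
  num <- rep(0, m)
  den <- 0
  for (mask in 0:(2^m - 1)) {
    if (!adj_is_transitive(mask_to_adj(mask, n))) next
    P <- mask_prob(mask, probs)
    den <- den + P
    e <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    num[e] <- num[e] + P
  }
  num / den
}

# count transitive graphs by exhaustive filtering (feasible for n <= 5)
brute_force_transitive_count <- function(n) {
  m <- n * (n - 1) / 2
  sum(vapply(0:(2^m - 1), function(mask)
    adj_is_transitive(mask_to_adj(mask, n)), logical(1)))
}

# the worked 3-node graph used throughout: p12 = p13 = 0.9, p23 = 0.1
worked_graph <- function() {
  ibd_graph_from_probs(c("1", "2", "3"), c(0.9, 0.9, 0.1))
}

# small canonical segment table builder
make_segs <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample1 = r[[1]], hap1 = as.integer(r[[2]]),
               sample2 = r[[3]], hap2 = as.integer(r[[4]]),
               chrom = as.character(r[[5]]), start_bp = as.numeric(r[[6]]),
               end_bp = as.numeric(r[[7]]), lod = as.numeric(r[[8]]),
               stringsAsFactors = FALSE)))
  ibd_segments(df)
}
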