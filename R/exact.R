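#' Bell numbers
#'
#' Number of set partitions of n labelled elements, which equals the
#' number of transitive IBD configurations on n nodes (every transitive
#' configuration is a partition of the haplotypes into cliques).
#'
#' @param n non-negative integer (vectorised).
#' @return numeric vector of Bell numbers.
#' @examples
#' bell_number(1:8)  # 1 2 5 15 52 203 877 4140
#' @export
bell_number <- function(n) {
  vapply(n, function(k) {
    if (k <= 1) return(1)
    # Bell triangle
    row <- 1
    for (i in seq_len(k - 1L)) row <- cumsum(c(row[length(row)], row))
    row[length(row)]
  }, numeric(1))
}

# All set partitions of n elements as restricted-growth strings:
# a B(n) x n integer matrix, block labels 1..k in order of first
# appearance. Row order is deterministic (lexicographic growth).
rgs_enumerate <- function(n) {
  stopifnot(n >= 1)
  parts <- matrix(1L, 1L, 1L)
  maxl <- 1L
  for (k in seq_len(n - 1L) + 1L) {
    # each partition with max label m expands into m + 1 children
    reps <- maxl + 1L
    idx <- rep(seq_len(nrow(parts)), each = max(reps)) # upper bound, filter below
    lab <- rep(seq_len(max(reps)), times = nrow(parts))
    keep <- lab <= rep(reps, each = max(reps))
    idx <- idx[keep]
    lab <- lab[keep]
    parts <- cbind(parts[idx, , drop = FALSE], lab)
    maxl <- pmax(maxl[idx], lab)
  }
  dimnames(parts) <- NULL
  parts
}

default_exact_cap <- 12L

#' Enumerate all transitive IBD configurations
#'
#' Generates every transitive configuration on `n` labelled nodes exactly
#' once. Transitive configurations are in bijection with set partitions of
#' the node set (each block a clique), so they are enumerated as
#' restricted-growth strings rather than by filtering all
#' `2^(n(n-1)/2)` graphs; the count is the Bell number B(n).
#'
#' @param n number of nodes.
#' @param nodes optional character node labels (defaults to `"1"..."n"`).
#' @param max_nodes refusal cap guarding against combinatorial explosion
#'   (default 12; B(12) is about 4.2 million).
#' @return list of [ibd_config()] objects, of length `bell_number(n)`.
#' @examples
#' length(enumerate_transitive(3))  # 5
#' @export
enumerate_transitive <- function(n, nodes = NULL,
                                 max_nodes = default_exact_cap) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (n > max_nodes)
    stop("refusing to enumerate transitive configurations on ", n,
         " nodes: the count is the Bell number B(", n, ") ~ ",
         format(bell_number(n), big.mark = ","),
         "; raise max_nodes to override")
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  parts <- rgs_enumerate(n)
  lapply(seq_len(nrow(parts)), function(r)
    ibd_config_from_membership(nodes, parts[r, ]))
}

#' Exact conditional IBD probabilities by enumeration
#'
#' Updates every pairwise IBD probability by conditioning on the whole
#' graph: the conditional probability of an edge is the summed probability
#' of all *transitive* configurations containing that edge divided by the
#' summed probability of all transitive configurations. Intransitive
#' configurations are excluded because they cannot represent a true state
#' of IBD. This routine is exact and serves as the reference for the
#' sampling approximation in [run_sampler()].
#'
#' @param G an [ibd_graph()] with all edge probabilities strictly inside
#'   (0, 1).
#' @param max_nodes refusal cap as in [enumerate_transitive()].
#' @return symmetric numeric matrix of conditional probabilities with the
#'   graph's node labels; diagonal `NA`.
#' @examples
#' G <- ibd_graph_from_probs(c("1", "2", "3"), c(0.9, 0.9, 0.1))
#' exact_conditionals(G)["2", "3"]  # 0.324 (to 3 decimals)
#' @export
exact_conditionals <- function(G, max_nodes = default_exact_cap) {
  stopifnot(inherits(G, "ibd_graph"))
  n <- length(G$nodes)
  if (n > max_nodes)
    stop("refusing exact conditionals on ", n,
         " nodes (cap ", max_nodes, "); use run_sampler() instead")
  up <- upper_pairs(n)
  p <- G$p[cbind(up$i, up$j)]
  if (any(p <= 0 | p >= 1))
    stop("exact conditionals require all probabilities strictly in (0, 1); ",
         "clamp or pin edges first")
  out <- matrix(NA_real_, n, n, dimnames = list(G$nodes, G$nodes))
  if (n == 1L) return(out)
  lp <- log(p)
  l1p <- log1p(-p)
  d <- lp - l1p
  base <- sum(l1p)
  parts <- rgs_enumerate(n)
  m <- length(p)
  # accumulate numerators/denominator in chunks so the presence matrix
  # (B(n) x m) never has to be materialised whole near the node cap
  num <- rep(-Inf, m)
  den <- -Inf
  chunk <- 200000L
  for (start in seq.int(1L, nrow(parts), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(parts))
    E <- matrix(FALSE, length(rows), m)
    for (k in seq_len(m))
      E[, k] <- parts[rows, up$i[k]] == parts[rows, up$j[k]]
    logP <- base + as.vector(E %*% d)
    den <- logaddexp(den, logsumexp(logP))
    for (k in seq_len(m)) {
      sel <- logP[E[, k]]
      if (length(sel)) num[k] <- logaddexp(num[k], logsumexp(sel))
    }
  }
  pdot <- ifelse(is.infinite(num), 0, exp(num - den))
  out[cbind(up$i, up$j)] <- pdot
  out[cbind(up$j, up$i)] <- pdot
  out
}
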