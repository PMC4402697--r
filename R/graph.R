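#' Haplotype identifiers
#'
#' A haplotype is one of the two phased chromosome copies of a diploid
#' individual and is the unit over which identity-by-descent (IBD) is
#' defined. Haplotypes are identified by a sample name plus a haplotype
#' index (1 or 2) and encoded as the string `"<sample>:<index>"`.
#' Ordering of haplotype ids is lexicographic on (sample, index) under C
#' collation, which fixes the canonical orientation of every edge key.
#'
#' @param sample character vector of sample identifiers (must not contain
#'   `":"`).
#' @param hap_index integer vector of haplotype indices, each 1 or 2.
#' @return character vector of haplotype ids.
#' @examples
#' hap_id("NA12878", 1)
#' @export
hap_id <- function(sample, hap_index) {
  if (any(grepl(":", sample, fixed = TRUE)))
    stop("sample identifiers must not contain ':'")
  hap_index <- as.integer(hap_index)
  if (any(!hap_index %in% c(1L, 2L)))
    stop("hap_index must be 1 or 2")
  paste(sample, hap_index, sep = ":")
}

#' @rdname hap_id
#' @param id character vector of haplotype ids produced by [hap_id()].
#' @return `parse_hap_id()`: a data.frame with columns `sample` and
#'   `hap_index`.
#' @export
parse_hap_id <- function(id) {
  pos <- regexpr(":[^:]*$", id)
  data.frame(sample = substr(id, 1L, pos - 1L),
             hap_index = as.integer(substr(id, pos + 1L, nchar(id))),
             stringsAsFactors = FALSE)
}

#' Probabilistic IBD graph
#'
#' A probabilistic IBD graph holds, for one genomic interval, a node per
#' haplotype and a probability of IBD for every unordered pair of nodes.
#' Pairs never called by the upstream pairwise caller carry the genome-wide
#' prior probability (epsilon, 0.0046 by default elsewhere in the package),
#' never exactly 0, so that every proposed configuration of the graph keeps
#' strictly positive probability.
#'
#' @param p symmetric numeric matrix of pairwise IBD probabilities in
#'   \[0, 1\]; the diagonal is ignored. Row/column names are used as node
#'   labels when `nodes` is not given.
#' @param nodes optional character vector of node labels (haplotype ids).
#' @param region optional list or vector with elements `chrom`, `start_bp`,
#'   `end_bp` recording the interval the graph describes.
#' @return an object of class `ibd_graph` with elements `nodes` (labels in
#'   canonical order), `p` (symmetric probability matrix, `NA` diagonal)
#'   and `region`.
#' @seealso [graph_probability()], [exact_conditionals()], [run_sampler()]
#' @examples
#' g <- ibd_graph_from_probs(c("1", "2", "3"), c(0.9, 0.9, 0.1))
#' g$p
#' @export
ibd_graph <- function(p, nodes = NULL, region = NULL) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("p must be square")
  if (is.null(nodes)) nodes <- rownames(p)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(p)))
  nodes <- as.character(nodes)
  if (length(nodes) != nrow(p)) stop("length(nodes) must match nrow(p)")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  dimnames(p) <- list(nodes, nodes)
  # canonical node order so edge keys are stable
  ord <- order(nodes, method = "radix")
  nodes <- nodes[ord]
  p <- p[ord, ord, drop = FALSE]
  diag(p) <- NA_real_
  off <- p[upper.tri(p)]
  if (anyNA(off)) stop("all off-diagonal probabilities must be set")
  if (any(off < 0 | off > 1)) stop("probabilities must lie in [0, 1]")
  if (max(abs(p - t(p)), na.rm = TRUE) > 1e-12)
    stop("p must be symmetric")
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(nodes = nodes, p = p, region = region),
            class = "ibd_graph")
}

#' @rdname ibd_graph
#' @param probs for `ibd_graph_from_probs()`: numeric vector of upper
#'   triangle probabilities in row-major pair order ((1,2), (1,3), ...,
#'   (2,3), ...) over `nodes` sorted canonically.
#' @export
ibd_graph_from_probs <- function(nodes, probs, region = NULL) {
  nodes <- sort_c(as.character(nodes))
  n <- length(nodes)
  m <- n * (n - 1L) / 2L
  if (length(probs) != m) stop("need ", m, " probabilities for ", n, " nodes")
  p <- matrix(0, n, n, dimnames = list(nodes, nodes))
  up <- upper_pairs(n)
  p[cbind(up$i, up$j)] <- probs
  p[cbind(up$j, up$i)] <- probs
  ibd_graph(p, nodes = nodes, region = region)
}

#' @export
print.ibd_graph <- function(x, ...) {
  cat("Probabilistic IBD graph:", length(x$nodes), "nodes,",
      choose(length(x$nodes), 2), "edges\n")
  if (!is.null(x$region))
    cat("  region:", x$region$chrom, x$region$start_bp, "-",
        x$region$end_bp, "\n")
  invisible(x)
}

#' Proposed IBD configurations
#'
#' A configuration is one concrete hypothesis about which haplotype pairs
#' are IBD at the locus: a binary edge assignment over the nodes of a
#' probabilistic IBD graph. A configuration is biologically plausible
#' (*transitive*) only when every connected component of its edges is a
#' complete clique, i.e. when it corresponds to a set partition of the
#' nodes.
#'
#' @param adj logical (or 0/1) symmetric adjacency matrix; the diagonal is
#'   ignored.
#' @param nodes optional character node labels, as for [ibd_graph()].
#' @return an object of class `ibd_config` with elements `nodes` and `adj`
#'   (logical symmetric matrix, `FALSE` diagonal).
#' @seealso [is_transitive()], [clique_close()], [graph_probability()]
#' @examples
#' cfg <- ibd_config_from_edges(c("1", "2", "3"), list(c("1", "2")))
#' is_transitive(cfg)
#' @export
ibd_config <- function(adj, nodes = NULL) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adj must be square")
  if (is.null(nodes)) nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adj)))
  nodes <- as.character(nodes)
  dimnames(adj) <- list(nodes, nodes)
  ord <- order(nodes, method = "radix")
  nodes <- nodes[ord]
  adj <- adj[ord, ord, drop = FALSE]
  mode(adj) <- "logical"
  if (!identical(adj, t(adj))) stop("adj must be symmetric")
  diag(adj) <- FALSE
  structure(list(nodes = nodes, adj = adj), class = "ibd_config")
}

#' @rdname ibd_config
#' @param edges list of length-2 character vectors naming the present
#'   edges.
#' @export
ibd_config_from_edges <- function(nodes, edges = list()) {
  nodes <- sort_c(as.character(nodes))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (e in edges) {
    if (length(e) != 2L || !all(e %in% nodes))
      stop("each edge must name two nodes of the configuration")
    adj[e[1L], e[2L]] <- TRUE
    adj[e[2L], e[1L]] <- TRUE
  }
  ibd_config(adj, nodes = nodes)
}

#' @rdname ibd_config
#' @param membership integer vector over `nodes`: nodes sharing a value
#'   form a clique. Defines the configuration whose components are exactly
#'   those cliques.
#' @export
ibd_config_from_membership <- function(nodes, membership) {
  nodes <- as.character(nodes)
  if (length(membership) != length(nodes))
    stop("membership must have one entry per node")
  adj <- outer(membership, membership, `==`)
  dimnames(adj) <- list(nodes, nodes)
  ibd_config(adj, nodes = nodes)
}

#' @export
print.ibd_config <- function(x, ...) {
  cat("IBD configuration:", length(x$nodes), "nodes,",
      sum(x$adj[upper.tri(x$adj)]), "edges;",
      if (is_transitive(x)) "transitive" else "intransitive", "\n")
  invisible(x)
}

check_same_nodes <- function(g, G) {
  if (!identical(g$nodes, G$nodes))
    stop("configuration and graph must share the same node set")
}

#' Probability of a configuration given a probabilistic IBD graph
#'
#' The probability of a proposed configuration g conditional on the
#' probabilistic graph is the product over all unordered node pairs of
#' `p_ij` when the edge is present and `1 - p_ij` when it is absent. The
#' product is accumulated in log space and exponentiated, so components
#' with hundreds of factors do not underflow prematurely.
#'
#' Edge probabilities exactly 0 or 1 are tolerated only when consistent
#' with the configuration (a pinned edge with p = 1 must be present, an
#' impossible edge with p = 0 must be absent); otherwise a domain error is
#' raised rather than silently returning 0.
#'
#' @param g an [ibd_config()].
#' @param G an [ibd_graph()] over the same node set.
#' @param log logical; return the log probability instead.
#' @return numeric scalar, the (log) probability of `g` given `G`.
#' @examples
#' G <- ibd_graph_from_probs(c("1", "2", "3"), c(0.9, 0.9, 0.1))
#' tri <- ibd_config_from_membership(c("1", "2", "3"), c(1, 1, 1))
#' graph_probability(tri, G)  # 0.9 * 0.9 * 0.1 = 0.081
#' @export
graph_probability <- function(g, G, log = FALSE) {
  check_same_nodes(g, G)
  n <- length(G$nodes)
  up <- upper_pairs(n)
  p <- G$p[cbind(up$i, up$j)]
  e <- g$adj[cbind(up$i, up$j)]
  if (any(p == 1 & !e))
    stop("edge with probability 1 absent from configuration")
  if (any(p == 0 & e))
    stop("edge with probability 0 present in configuration")
  lp <- ifelse(e, log(p), log1p(-p))
  lp[(p == 1 & e) | (p == 0 & !e)] <- 0
  out <- sum(lp)
  if (log) out else exp(out)
}

# membership vector of connected components (integer labels, arbitrary)
component_membership <- function(adj) {
  n <- nrow(adj)
  memb <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (memb[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    memb[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & memb == 0L)
      memb[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  memb
}

#' Transitivity of an IBD configuration
#'
#' A configuration can represent a true state of IBD at a locus only if
#' IBD sharing is transitive: whenever haplotypes a-b and b-c share, a-c
#' must share too. Equivalently every connected component of the present
#' edges must be a complete clique.
#'
#' @param g an [ibd_config()].
#' @return logical scalar.
#' @examples
#' is_transitive(ibd_config_from_edges(c("1", "2", "3"),
#'                                     list(c("1", "2"), c("1", "3"))))
#' @export
is_transitive <- function(g) {
  memb <- component_membership(g$adj)
  full <- outer(memb, memb, `==`)
  diag(full) <- FALSE
  identical(unname(g$adj), unname(full))
}

#' Connected components of a configuration
#'
#' @param g an [ibd_config()].
#' @return list of character vectors, one per component, each sorted; the
#'   components are ordered by their smallest member so output is
#'   deterministic.
#' @export
connected_components <- function(g) {
  memb <- component_membership(g$adj)
  comps <- split(g$nodes, memb)
  comps <- lapply(comps, sort_c)
  comps <- comps[order(vapply(comps, `[`, "", 1L), method = "radix")]
  unname(comps)
}

#' Clique closure of a configuration
#'
#' Returns the minimal transitive configuration containing the edges of
#' `g`: within every connected component all pairwise edges are switched
#' on; no cross-component edge is ever added. Idempotent.
#'
#' @param g an [ibd_config()].
#' @return an [ibd_config()] that satisfies [is_transitive()].
#' @export
clique_close <- function(g) {
  memb <- component_membership(g$adj)
  ibd_config_from_membership(g$nodes, memb)
}
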