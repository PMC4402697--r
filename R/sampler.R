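#' Edge-selection weight parameters
#'
#' Edges are proposed for flipping with probability proportional to a
#' bell-shaped weight centred at p = 0.5: near-certain edges (p close to
#' 0 or 1) are informative only rarely, while uncertain edges drive the
#' exploration of configuration space. The weight is the normal CDF of p
#' below 0.5 and its mirror image above.
#'
#' @param mu location of the weighting curve (default 0.5).
#' @param sigma scale of the weighting curve (default 0.234, chosen for
#'   efficient convergence).
#' @return list with class `weight_params`.
#' @export
weight_params <- function(mu = 0.5, sigma = 0.234) {
  stopifnot(sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "weight_params")
}

#' @rdname weight_params
#' @param p numeric vector of edge probabilities in \[0, 1\].
#' @param params a [weight_params()].
#' @return `edge_weight()`: numeric vector of selection weights, strictly
#'   positive for p in (0, 1), symmetric about 0.5 when `mu = 0.5`.
#' @examples
#' edge_weight(0.5)  # 0.5
#' edge_weight(c(0.1, 0.9))  # equal, ~0.0436
#' @export
edge_weight <- function(p, params = weight_params()) {
  stopifnot(all(p >= 0 & p <= 1))
  phi <- stats::pnorm(p, mean = params$mu, sd = params$sigma)
  ifelse(p <= 0.5, phi, 1 - phi)
}

#' Sampler configuration
#'
#' @param fixed_edge_threshold probability at or above which an edge is
#'   pinned present (treated as probability 1, never proposed for
#'   flipping). Default 0.99.
#' @param convergence_tol per-edge change in the running estimate below
#'   which an iteration counts as stable (default 1e-11).
#' @param convergence_window number of consecutive stable iterations
#'   required to declare convergence (default 5000).
#' @param max_seconds wall-clock cap per graph (default 120).
#' @param max_iterations optional hard iteration cap (default `NULL`,
#'   i.e. run until convergence or the time cap).
#' @param seed optional integer; when given, [run_sampler()] seeds the
#'   RNG so the whole estimate trajectory is reproducible.
#' @param accumulate `"distinct"` (default) adds each distinct transitive
#'   configuration's probability mass to the accumulators once, the first
#'   time it is visited, so the estimate converges to the exact
#'   enumeration ratio as coverage of configuration space grows;
#'   `"all"` re-accumulates on every visit (see the methods vignette for
#'   why `"distinct"` is the default).
#' @return list with class `sampler_config`.
#' @export
sampler_config <- function(fixed_edge_threshold = 0.99,
                           convergence_tol = 1e-11,
                           convergence_window = 5000L,
                           max_seconds = 120,
                           max_iterations = NULL,
                           seed = NULL,
                           accumulate = c("distinct", "all")) {
  stopifnot(fixed_edge_threshold > 0, fixed_edge_threshold <= 1,
            convergence_tol > 0, convergence_window >= 1)
  structure(list(fixed_edge_threshold = fixed_edge_threshold,
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 max_seconds = max_seconds,
                 max_iterations = if (!is.null(max_iterations))
                   as.integer(max_iterations),
                 seed = seed,
                 accumulate = match.arg(accumulate)),
            class = "sampler_config")
}

#' Initial configuration for the sampler
#'
#' Pins every edge whose probability reaches the fixed-edge threshold,
#' then clique-closes, so sampling starts from the transitive
#' configuration implied by the near-certain calls.
#'
#' @param G an [ibd_graph()].
#' @param config a [sampler_config()].
#' @return a transitive [ibd_config()].
#' @export
initialize_configuration <- function(G, config = sampler_config()) {
  adj <- !is.na(G$p) & G$p >= config$fixed_edge_threshold
  clique_close(ibd_config(adj, nodes = G$nodes))
}

#' Transitivity repair after switching an edge on
#'
#' Adding an edge can merge two cliques into one connected component that
#' is no longer complete; the repair is the clique closure of the merged
#' component. Cheap and deterministic.
#'
#' @param g an [ibd_config()] in which `edge` has just been set present.
#' @param edge length-2 character vector naming the flipped edge.
#' @return a transitive [ibd_config()].
#' @export
repair_after_add <- function(g, edge) {
  if (!all(edge %in% g$nodes)) stop("edge endpoints not in configuration")
  clique_close(g)
}

# --- internal membership-vector machinery -------------------------------
# A transitive configuration over nodes 1..n is a partition; we keep it as
# an integer membership vector with the invariant memb[v] == min(block of v),
# which makes the vector itself a canonical key for the partition.

memb_canonical <- function(memb) {
  for (b in unique(memb)) {
    members <- which(memb == b)
    memb[members] <- min(members)
  }
  memb
}

memb_merge <- function(memb, i, j) {
  sel <- memb == memb[i] | memb == memb[j]
  memb[sel] <- min(which(sel))
  memb
}

# Algorithm-2 style removal repair. memb[i] == memb[j] is required.
# pmat: full probability matrix; pin_adj: logical adjacency of pinned edges.
# Uses the global RNG for tie coins and the singleton visitation order.
memb_remove_repair <- function(memb, i, j, pmat, pin_adj) {
  blk <- which(memb == memb[i])
  # step 1: inside the component, clear all non-pinned edges; what is left
  # are the welded sub-cliques
  sub <- component_membership(pin_adj[blk, blk, drop = FALSE])
  ci <- sub[match(i, blk)]
  cj <- sub[match(j, blk)]
  if (ci == cj) {
    # i and j are welded together by pinned edges: the removal cannot be
    # realised and closure reunites the whole block
    return(memb)
  }
  si <- blk[sub == ci]
  sj <- blk[sub == cj]
  groups <- split(blk, sub)
  rest <- groups[!names(groups) %in% c(ci, cj)]
  singles <- integer(0)
  for (x in rest) {
    if (length(x) > 1L) {
      # step 2: welded multi-node groups join the side they are closer to
      pbar_i <- mean(pmat[i, x])
      pbar_j <- mean(pmat[j, x])
      if (pbar_i > pbar_j) si <- c(si, x)
      else if (pbar_i < pbar_j) sj <- c(sj, x)
      else if (stats::runif(1) < 0.5) si <- c(si, x)
      else sj <- c(sj, x)
    } else {
      singles <- c(singles, x)
    }
  }
  # step 3: leftover single nodes, in random order, join the side whose
  # current members they are on average closer to
  if (length(singles)) {
    ord <- if (length(singles) > 1L) sample(singles) else singles
    for (k in ord) {
      pbar_ki <- mean(pmat[k, si])
      pbar_kj <- mean(pmat[k, sj])
      if (pbar_ki > pbar_kj) si <- c(si, k)
      else if (pbar_ki < pbar_kj) sj <- c(sj, k)
      else if (stats::runif(1) < 0.5) si <- c(si, k)
      else sj <- c(sj, k)
    }
  }
  # step 4: both sides become cliques
  memb[si] <- min(si)
  memb[sj] <- min(sj)
  memb
}

#' Transitivity repair after switching an edge off
#'
#' Removing an edge from a clique leaves an incomplete component. The
#' repair splits the component into two cliques anchored at the removed
#' edge's endpoints: edges pinned by the fixed-edge threshold survive as
#' welded sub-cliques assigned wholesale to the nearer side (mean edge
#' probability to each endpoint), remaining nodes join sides one at a
#' time in random order by mean probability to the side's current
#' members, and exact ties are settled by a fair coin. The repaired
#' configuration keeps the flipped edge absent unless its endpoints are
#' welded together by pinned edges, in which case the split is impossible
#' and the component is restored whole.
#'
#' Tie coins and the node visitation order come from R's global RNG;
#' seed it (or use the `seed` field of [sampler_config()] inside
#' [run_sampler()]) for reproducibility.
#'
#' @param g an [ibd_config()] in which `edge` was present before removal.
#' @param G the [ibd_graph()] supplying edge probabilities.
#' @param edge length-2 character vector naming the removed edge.
#' @param config a [sampler_config()] (supplies the fixed-edge
#'   threshold).
#' @return a transitive [ibd_config()].
#' @export
repair_after_remove <- function(g, G, edge, config = sampler_config()) {
  check_same_nodes(g, G)
  i <- match(edge[1L], g$nodes)
  j <- match(edge[2L], g$nodes)
  if (is.na(i) || is.na(j)) stop("edge endpoints not in configuration")
  memb <- memb_canonical(component_membership(g$adj))
  if (memb[i] != memb[j])
    stop("edge (", edge[1L], ", ", edge[2L],
         ") was not inside a single component before removal")
  pin_adj <- !is.na(G$p) & G$p >= config$fixed_edge_threshold
  memb <- memb_remove_repair(memb, i, j, G$p, pin_adj)
  ibd_config_from_membership(g$nodes, memb)
}

#' Approximate conditional IBD probabilities by graph sampling
#'
#' Estimates the conditional probability of every edge given the whole
#' probabilistic IBD graph by sampling transitive configurations instead
#' of enumerating them. Starting from the pinned-edge configuration, each
#' iteration proposes one non-pinned edge (selected with probability
#' proportional to [edge_weight()]), switches it on with probability
#' `p_ij` and off otherwise, repairs transitivity
#' ([repair_after_add()] / [repair_after_remove()]), and adds the
#' configuration's probability mass to a running total `N_g` and to
#' per-edge totals `N_ij` for the edges present. The estimate at any
#' point is `p_hat = N_ij / N_g`, which approaches the exact enumeration
#' ratio of [exact_conditionals()] as the sampled configurations cover
#' the high-probability part of configuration space.
#'
#' Accumulation is carried in log space, so components with many nodes do
#' not underflow. Pinned edges (p at or above the fixed-edge threshold)
#' are treated as probability exactly 1: always present, never proposed,
#' and reported with `p_hat = 1`.
#'
#' @param G an [ibd_graph()].
#' @param config a [sampler_config()].
#' @param weights a [weight_params()].
#' @param record_iterations optional integer vector of iteration numbers
#'   at which to snapshot the estimate matrix (used for convergence
#'   traces).
#' @return list with elements:
#'   * `p_hat`: symmetric matrix of estimated conditional probabilities;
#'   * `state`: list with `log_n_g`, `log_n_ij` (named vector over edge
#'     keys `"a|b"`), `iterations`, `converged`, `timed_out`,
#'     `distinct_configs`, `pinned` (logical matrix);
#'   * `snapshots`: named list of estimate matrices, one per recorded
#'     iteration.
#' @examples
#' G <- ibd_graph_from_probs(c("1", "2", "3"), c(0.9, 0.9, 0.1))
#' fit <- run_sampler(G, sampler_config(seed = 1, max_iterations = 5000))
#' round(fit$p_hat["2", "3"], 3)
#' @export
run_sampler <- function(G, config = sampler_config(),
                        weights = weight_params(),
                        record_iterations = NULL) {
  stopifnot(inherits(G, "ibd_graph"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(G$nodes)
  up <- upper_pairs(n)
  m <- length(up$i)
  empty <- matrix(NA_real_, n, n, dimnames = list(G$nodes, G$nodes))
  if (m == 0L)
    return(list(p_hat = empty,
                state = list(log_n_g = 0, log_n_ij = numeric(0),
                             iterations = 0L, converged = TRUE,
                             timed_out = FALSE, distinct_configs = 1L,
                             pinned = empty),
                snapshots = list()))
  pvec <- G$p[cbind(up$i, up$j)]
  pinned <- pvec >= config$fixed_edge_threshold
  np <- !pinned
  if (any(pvec[np] <= 0 | pvec[np] >= 1))
    stop("non-pinned edge probabilities must lie strictly in (0, 1)")
  # log-probability pieces; pinned edges contribute factor 1 exactly
  dn <- numeric(m)
  base <- 0
  if (any(np)) {
    lp <- log(pvec[np])
    l1p <- log1p(-pvec[np])
    dn[np] <- lp - l1p
    base <- sum(l1p)
  }
  edge_keys <- paste(G$nodes[up$i], G$nodes[up$j], sep = "|")

  # initial configuration: pinned edges, clique-closed
  adj <- matrix(FALSE, n, n)
  adj[cbind(up$i, up$j)[pinned, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  memb <- memb_canonical(component_membership(adj))

  pres <- memb[up$i] == memb[up$j]
  log_pg <- base + sum(dn[pres])
  log_ng <- log_pg
  log_nij <- rep(-Inf, m)
  log_nij[pres] <- log_pg
  p_hat <- exp(log_nij - log_ng)
  dedupe <- config$accumulate == "distinct"
  visited <- new.env(parent = emptyenv(), size = 1024L)
  if (dedupe) assign(paste(memb, collapse = ","), TRUE, envir = visited)
  n_distinct <- 1L

  record_iterations <- sort(unique(as.integer(record_iterations %||%
                                                integer(0))))
  snapshots <- list()
  take_snapshot <- function(it) {
    mm <- empty
    mm[cbind(up$i, up$j)] <- p_hat
    mm[cbind(up$j, up$i)] <- p_hat
    snapshots[[as.character(it)]] <<- mm
  }

  cand <- which(np)
  converged <- FALSE
  timed_out <- FALSE
  iter <- 0L
  if (length(cand)) {
    w <- edge_weight(pvec[cand], weights)
    t0 <- Sys.time()
    tol <- config$convergence_tol
    window <- config$convergence_window
    stable <- 0L
    max_iter <- config$max_iterations %||% .Machine$integer.max
    batch <- 10000L
    picks <- integer(0)
    us <- numeric(0)
    bpos <- 0L
    while (iter < max_iter) {
      if (bpos >= length(picks)) {
        nb <- min(batch, max_iter - iter)
        picks <- sample.int(length(cand), nb, replace = TRUE, prob = w)
        us <- stats::runif(nb)
        bpos <- 0L
      }
      bpos <- bpos + 1L
      iter <- iter + 1L
      k <- cand[picks[bpos]]
      i <- up$i[k]
      j <- up$j[k]
      to_one <- us[bpos] < pvec[k]
      same <- memb[i] == memb[j]
      changed <- FALSE
      if (to_one && !same) {
        memb <- memb_merge(memb, i, j)
        changed <- TRUE
      } else if (!to_one && same) {
        new_memb <- memb_remove_repair(memb, i, j, G$p, adj)
        changed <- !identical(new_memb, memb)
        memb <- new_memb
      }
      if (changed) {
        pres <- memb[up$i] == memb[up$j]
        log_pg <- base + sum(dn[pres])
      }
      do_acc <- TRUE
      if (dedupe) {
        key <- paste(memb, collapse = ",")
        if (is.null(visited[[key]])) {
          assign(key, TRUE, envir = visited)
          n_distinct <- n_distinct + 1L
        } else {
          do_acc <- FALSE
        }
      }
      if (do_acc) {
        log_ng <- logaddexp(log_ng, log_pg)
        log_nij[pres] <- logaddexp(log_nij[pres], log_pg)
        p_new <- exp(log_nij - log_ng)
        delta <- max(abs(p_new - p_hat))
        p_hat <- p_new
      } else {
        delta <- 0
      }
      stable <- if (delta < tol) stable + 1L else 0L
      if (length(record_iterations) && iter %in% record_iterations)
        take_snapshot(iter)
      if (stable >= window) {
        converged <- TRUE
        break
      }
      if (as.numeric(difftime(Sys.time(), t0, units = "secs")) >
          config$max_seconds) {
        timed_out <- TRUE
        break
      }
    }
  } else {
    converged <- TRUE
  }

  p_hat[pinned] <- 1
  out <- empty
  out[cbind(up$i, up$j)] <- p_hat
  out[cbind(up$j, up$i)] <- p_hat
  pin_mat <- empty
  pin_mat[cbind(up$i, up$j)] <- pinned
  pin_mat[cbind(up$j, up$i)] <- pinned
  names(log_nij) <- edge_keys
  list(p_hat = out,
       state = list(log_n_g = log_ng, log_n_ij = log_nij,
                    iterations = iter, converged = converged,
                    timed_out = timed_out, distinct_configs = n_distinct,
                    pinned = pin_mat == 1),
       snapshots = snapshots)
}
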