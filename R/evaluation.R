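#' Convergence diagnostic between exact and sampled conditionals
#'
#' The mean, over non-pinned edges, of the relative difference between
#' the exact conditional probability and the sampling estimate,
#' expressed in percent. Pinned edges are excluded because they are not
#' estimated.
#'
#' @param exact symmetric matrix of exact conditionals
#'   ([exact_conditionals()]).
#' @param estimate symmetric matrix of estimates ([run_sampler()]
#'   `p_hat` or a snapshot).
#' @param pinned optional logical matrix marking pinned edges to
#'   exclude.
#' @return numeric scalar, the mean relative percent difference.
#' @examples
#' convergence_delta(matrix(c(NA, .5, .5, NA), 2),
#'                   matrix(c(NA, .45, .45, NA), 2))  # 10
#' @export
convergence_delta <- function(exact, estimate, pinned = NULL) {
  stopifnot(identical(dim(exact), dim(estimate)))
  n <- nrow(exact)
  up <- upper_pairs(n)
  idx <- cbind(up$i, up$j)
  v <- exact[idx]
  e <- estimate[idx]
  keep <- rep(TRUE, length(v))
  if (!is.null(pinned)) keep <- !pinned[idx]
  v <- v[keep]
  e <- e[keep]
  if (any(v == 0)) stop("exact conditionals of zero cannot be compared ",
                        "relatively")
  mean(abs(v - e) / v) * 100
}

#' Convergence experiment on random graphs
#'
#' Protocol for validating the sampler against the enumeration oracle:
#' draw a complete random graph with Uniform(0, 0.99) edge
#' probabilities, compute exact conditionals by enumeration, run the
#' sampler `runs` times with distinct seeds, and report the
#' run-averaged [convergence_delta()] at the requested iteration
#' checkpoints.
#'
#' @param n number of nodes (enumeration must be feasible; n <= 8 takes
#'   seconds).
#' @param runs number of independent sampler runs (default 25).
#' @param iterations integer vector of checkpoints (default
#'   `c(5000, 7500)`).
#' @param graph optional [ibd_graph()] to use instead of drawing one.
#' @param seed integer seed governing both the graph draw and the run
#'   seeds.
#' @return data.frame with columns `iteration`, `delta_bar` (mean over
#'   runs) and `delta_sd`.
#' @export
convergence_experiment <- function(n, runs = 25L,
                                   iterations = c(5000L, 7500L),
                                   graph = NULL, seed = 1L) {
  set.seed(seed)
  G <- graph %||% random_ibd_graph(n)
  ex <- exact_conditionals(G)
  iterations <- sort(unique(as.integer(iterations)))
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)
  deltas <- matrix(NA_real_, runs, length(iterations))
  for (r in seq_len(runs)) {
    fit <- run_sampler(G, sampler_config(seed = run_seeds[r],
                                         max_iterations = max(iterations),
                                         max_seconds = Inf),
                       record_iterations = iterations)
    for (k in seq_along(iterations)) {
      snap <- fit$snapshots[[as.character(iterations[k])]] %||% fit$p_hat
      deltas[r, k] <- convergence_delta(ex, snap,
                                        pinned = fit$state$pinned)
    }
  }
  data.frame(iteration = iterations,
             delta_bar = colMeans(deltas),
             delta_sd = apply(deltas, 2L, stats::sd))
}

seg_len_bin <- function(len_cm, width = 0.1) {
  floor(len_cm / width + 1e-9) * width
}

overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Segment-level benchmarking metrics
#'
#' Compares a predicted call set against ground truth on the same
#' haplotype-pair universe, using at least 1 bp of overlap on the same
#' pair as "intersecting". Two tables are produced, binned by genetic
#' length (left-closed bins labelled by their lower edge):
#'
#' * by predicted-segment size: `n_predicted`, `n_intersecting` (count
#'   overlapping any true segment), `error_rate` (fraction overlapping
#'   none), `fdr_proportion` (mean proportion of predicted length not
#'   covered by truth), `tp50_rate` (fraction with at least 50% of
#'   their length covered by one true segment's overlap).
#' * by true-segment size: `n_true`, `power` (mean proportion of the
#'   true segment covered by predictions).
#'
#' @param predicted,truth [ibd_segments()] data.frames; truth should
#'   contain segments of at least 0.1 cM.
#' @param map optional genetic map for lengths.
#' @param bin_width_cm bin width (default 0.1 cM).
#' @return list with data.frames `by_predicted` and `by_truth`.
#' @export
segment_metrics <- function(predicted, truth, map = NULL,
                            bin_width_cm = 0.1) {
  predicted <- ibd_segments(predicted)
  truth <- ibd_segments(truth)
  plen <- segment_length_cm(predicted, map)
  tlen <- segment_length_cm(truth, map)
  pkey <- paste(predicted$hap_a, predicted$hap_b, predicted$chrom)
  tkey <- paste(truth$hap_a, truth$hap_b, truth$chrom)
  tsplit <- split(seq_len(nrow(truth)), tkey)

  covered_prop <- numeric(nrow(predicted))
  best_single <- numeric(nrow(predicted))
  for (r in seq_len(nrow(predicted))) {
    cand <- tsplit[[pkey[r]]]
    if (is.null(cand)) next
    ov <- overlap_bp(predicted$start_bp[r], predicted$end_bp[r],
                     truth$start_bp[cand], truth$end_bp[cand])
    cand <- cand[ov > 0]
    ov <- ov[ov > 0]
    if (!length(cand)) next
    best_single[r] <- max(ov)
    covered_prop[r] <- covered_union(predicted$start_bp[r],
                                     predicted$end_bp[r],
                                     truth$start_bp[cand],
                                     truth$end_bp[cand])
  }
  plen_bp <- predicted$end_bp - predicted$start_bp + 1
  intersects <- covered_prop > 0
  tp50 <- best_single >= 0.5 * plen_bp

  psplit <- split(seq_len(nrow(predicted)), pkey)
  tcov <- numeric(nrow(truth))
  for (r in seq_len(nrow(truth))) {
    cand <- psplit[[tkey[r]]]
    if (is.null(cand)) next
    tcov[r] <- covered_union(truth$start_bp[r], truth$end_bp[r],
                             predicted$start_bp[cand],
                             predicted$end_bp[cand])
  }

  pbin <- seg_len_bin(plen, bin_width_cm)
  tbin <- seg_len_bin(tlen, bin_width_cm)
  by_pred <- do.call(rbind, lapply(sort(unique(pbin)), function(b) {
    sel <- pbin == b
    data.frame(bin_cm = b, n_predicted = sum(sel),
               n_intersecting = sum(intersects[sel]),
               error_rate = mean(!intersects[sel]),
               fdr_proportion = mean(1 - covered_prop[sel]),
               tp50_rate = mean(tp50[sel]))
  }))
  by_truth <- do.call(rbind, lapply(sort(unique(tbin)), function(b) {
    sel <- tbin == b
    data.frame(bin_cm = b, n_true = sum(sel), power = mean(tcov[sel]))
  }))
  list(by_predicted = by_pred %||%
         data.frame(bin_cm = numeric(0), n_predicted = integer(0),
                    n_intersecting = integer(0), error_rate = numeric(0),
                    fdr_proportion = numeric(0), tp50_rate = numeric(0)),
       by_truth = by_truth %||%
         data.frame(bin_cm = numeric(0), n_true = integer(0),
                    power = numeric(0)))
}

# proportion of [s, e] covered by the union of [ss_i, ee_i]
covered_union <- function(s, e, ss, ee) {
  ss <- pmax(ss, s)
  ee <- pmin(ee, e)
  keep <- ss <= ee
  ss <- ss[keep]
  ee <- ee[keep]
  if (!length(ss)) return(0)
  ord <- order(ss)
  ss <- ss[ord]
  ee <- ee[ord]
  tot <- 0
  cs <- ss[1L]
  ce <- ee[1L]
  for (k in seq_along(ss)[-1L]) {
    if (ss[k] <= ce + 1) ce <- max(ce, ee[k])
    else {
      tot <- tot + ce - cs + 1
      cs <- ss[k]
      ce <- ee[k]
    }
  }
  tot <- tot + ce - cs + 1
  tot / (e - s + 1)
}

#' Clique recovery metrics at a locus
#'
#' Given a predicted IBD configuration and the true partition of
#' haplotypes into cliques at one locus:
#'
#' * edge power, per true-clique-size bin: the mean over true cliques of
#'   the proportion of their within-clique edges present in the
#'   prediction;
#' * false-positive rate, per predicted-clique-size bin: the mean over
#'   predicted components of the proportion of their edges joining nodes
#'   that are not together in any true clique.
#'
#' @param predicted an [ibd_config()] (or logical adjacency matrix with
#'   node dimnames).
#' @param truth_partition list of character vectors: the true cliques
#'   (singletons may be omitted).
#' @param size_breaks numeric breaks for clique-size bins (default
#'   `c(2, 4, 6, 9, 30, 60, 90, 120, 150)`, left-closed).
#' @return list with data.frames `edge_power` (bin, n_cliques, power)
#'   and `false_positive` (bin, n_components, fp_rate).
#' @export
clique_metrics <- function(predicted, truth_partition,
                           size_breaks = c(2, 4, 6, 9, 30, 60, 90, 120,
                                           150)) {
  if (!inherits(predicted, "ibd_config"))
    predicted <- ibd_config(predicted)
  nodes <- predicted$nodes
  truth_partition <- lapply(truth_partition, as.character)
  tm <- rep(NA_integer_, length(nodes))
  names(tm) <- nodes
  for (k in seq_along(truth_partition)) {
    mem <- intersect(truth_partition[[k]], nodes)
    tm[mem] <- k
  }
  bin_of <- function(sz) {
    b <- size_breaks[findInterval(sz, size_breaks)]
    ifelse(is.na(b), size_breaks[1L], b)
  }
  # power per true clique
  pw <- lapply(seq_along(truth_partition), function(k) {
    mem <- intersect(truth_partition[[k]], nodes)
    if (length(mem) < 2L) return(NULL)
    pairs <- utils::combn(mem, 2L)
    hit <- mapply(function(a, b) predicted$adj[a, b],
                  pairs[1L, ], pairs[2L, ])
    data.frame(size = length(mem), power = mean(hit))
  })
  pw <- do.call(rbind, pw)
  edge_power <- if (is.null(pw))
    data.frame(bin = numeric(0), n_cliques = integer(0), power = numeric(0))
  else {
    pw$bin <- bin_of(pw$size)
    do.call(rbind, lapply(sort(unique(pw$bin)), function(b)
      data.frame(bin = b, n_cliques = sum(pw$bin == b),
                 power = mean(pw$power[pw$bin == b]))))
  }
  # false positives per predicted component
  comps <- connected_components(predicted)
  fp <- lapply(comps, function(mem) {
    if (length(mem) < 2L) return(NULL)
    pairs <- utils::combn(mem, 2L)
    pred_edge <- mapply(function(a, b) predicted$adj[a, b],
                        pairs[1L, ], pairs[2L, ])
    same_true <- mapply(function(a, b)
      !is.na(tm[a]) && !is.na(tm[b]) && tm[a] == tm[b],
      pairs[1L, ], pairs[2L, ])
    data.frame(size = length(mem),
               fp = mean(!same_true[pred_edge]))
  })
  fp <- do.call(rbind, fp)
  false_positive <- if (is.null(fp))
    data.frame(bin = numeric(0), n_components = integer(0),
               fp_rate = numeric(0))
  else {
    fp$bin <- bin_of(fp$size)
    do.call(rbind, lapply(sort(unique(fp$bin)), function(b)
      data.frame(bin = b, n_components = sum(fp$bin == b),
                 fp_rate = mean(fp$fp[fp$bin == b]))))
  }
  list(edge_power = edge_power, false_positive = false_positive)
}
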