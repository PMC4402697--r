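#' Random probabilistic IBD graph
#'
#' Complete graph with i.i.d. Uniform(0, `upper`) edge probabilities,
#' the input distribution used by the sampler validation experiments.
#' The default upper bound 0.99 keeps every edge strictly below the
#' sampler's pinning threshold.
#'
#' @param n number of nodes (>= 2).
#' @param seed optional integer seed for reproducibility.
#' @param upper upper bound of the uniform distribution (default 0.99).
#' @return an [ibd_graph()].
#' @export
random_ibd_graph <- function(n, seed = NULL, upper = 0.99) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  m <- n * (n - 1L) / 2L
  probs <- stats::runif(m, 0, upper)
  probs[probs == 0] <- .Machine$double.eps  # open interval
  ibd_graph_from_probs(as.character(seq_len(n)), probs)
}

#' Simulate ground-truth IBD cliques and segments
#'
#' Places clique events along one chromosome: event positions follow a
#' Poisson process, each event selects a clique size and a genetic
#' length and contributes all pairwise true segments between its member
#' haplotypes over one shared interval. Members are drawn only from
#' haplotypes with no other true segment overlapping the interval, so at
#' every locus the implied IBD graph is a disjoint union of cliques
#' (exactly transitive by construction) — the structure the graph
#' conditioning exploits.
#'
#' Default rates emulate the statistical structure of array-based IBD
#' call sets in an expanding population: clique sizes 2-8 with halving
#' frequency, exponential segment lengths with mean 0.8 cM, and a
#' uniform 1 cM/Mb genetic map.
#'
#' @param n_haplotypes number of haplotypes (2 per sample; default 200).
#' @param chrom chromosome label (default "1").
#' @param chrom_length_bp chromosome length (default 30 Mb).
#' @param cliques_per_mb expected clique events per Mb (default 2).
#' @param clique_size_probs named or plain numeric vector of weights for
#'   clique sizes starting at 2 (default `2^-(0:6)` over sizes 2-8).
#' @param mean_len_cm mean of the exponential segment-length
#'   distribution in cM (default 0.8).
#' @param min_len_cm truth segments shorter than this are discarded
#'   (default 0.1 cM, the conventional lower bound for a true segment).
#' @param seed optional integer seed.
#' @return list of class `ibd_truth` with elements `segments` (an
#'   [ibd_segments()] data.frame with `prob = 1`, no LOD), `cliques`
#'   (data.frame: `clique`, `hap`, `start_bp`, `end_bp`) and `params`.
#' @export
simulate_ibd_truth <- function(n_haplotypes = 200L, chrom = "1",
                               chrom_length_bp = 30e6,
                               cliques_per_mb = 2,
                               clique_size_probs = 2^-(0:6),
                               mean_len_cm = 0.8, min_len_cm = 0.1,
                               seed = NULL) {
  stopifnot(n_haplotypes >= 4, chrom_length_bp > 0, cliques_per_mb >= 0)
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("S%04d", seq_len(ceiling(n_haplotypes / 2)))
  haps <- sort_c(as.vector(outer(samples, 1:2, hap_id)))[seq_len(n_haplotypes)]
  sizes <- seq.int(2L, 1L + length(clique_size_probs))
  n_events <- stats::rpois(1L, cliques_per_mb * chrom_length_bp / 1e6)
  segs <- list()
  cliques <- list()
  # busy[[hap]] holds intervals already claimed by a clique for that hap
  busy <- new.env(parent = emptyenv())
  n_kept <- 0L
  if (n_events > 0) for (ev in seq_len(n_events)) {
    k <- sample(sizes, 1L, prob = clique_size_probs)
    len_cm <- stats::rexp(1L, rate = 1 / mean_len_cm)
    if (len_cm < min_len_cm) next
    len_bp <- round(len_cm * 1e6)  # 1 cM/Mb
    if (len_bp >= chrom_length_bp) next
    start <- floor(stats::runif(1L, 1, chrom_length_bp - len_bp))
    end <- start + len_bp - 1
    free <- vapply(haps, function(h) {
      iv <- busy[[h]]
      is.null(iv) || all(iv$end < start | iv$start > end)
    }, logical(1))
    if (sum(free) < k) next
    members <- sort_c(sample(haps[free], k))
    for (h in members) {
      iv <- busy[[h]]
      busy[[h]] <- rbind(iv, data.frame(start = start, end = end))
    }
    n_kept <- n_kept + 1L
    cliques[[n_kept]] <- data.frame(clique = n_kept, hap = members,
                                    start_bp = start, end_bp = end,
                                    stringsAsFactors = FALSE)
    pr <- utils::combn(members, 2L)
    ida <- parse_hap_id(pr[1L, ])
    idb <- parse_hap_id(pr[2L, ])
    segs[[n_kept]] <- data.frame(sample1 = ida$sample, hap1 = ida$hap_index,
                                 sample2 = idb$sample, hap2 = idb$hap_index,
                                 chrom = chrom, start_bp = start,
                                 end_bp = end, lod = NA_real_, prob = 1,
                                 inferred = FALSE, stringsAsFactors = FALSE)
  }
  segments <- if (length(segs)) ibd_segments(do.call(rbind, segs)) else
    ibd_segments(data.frame(sample1 = character(0), hap1 = integer(0),
                            sample2 = character(0), hap2 = integer(0),
                            chrom = character(0), start_bp = numeric(0),
                            end_bp = numeric(0), lod = numeric(0),
                            prob = numeric(0)))
  structure(list(segments = segments,
                 cliques = if (length(cliques)) do.call(rbind, cliques)
                   else NULL,
                 params = list(n_haplotypes = n_haplotypes, chrom = chrom,
                               chrom_length_bp = chrom_length_bp,
                               cliques_per_mb = cliques_per_mb,
                               mean_len_cm = mean_len_cm,
                               min_len_cm = min_len_cm, seed = seed)),
            class = "ibd_truth")
}

#' Default detection curve for the noisy call emitter
#'
#' Logistic detection probability as a function of genetic length,
#' emulating the decay of pairwise-caller power on short segments:
#' about 0.2 at 0.1 cM, 0.9 at 0.5 cM, and essentially 1 beyond 1 cM.
#'
#' @param len_cm numeric vector of segment lengths in cM.
#' @return detection probabilities.
#' @export
default_detection <- function(len_cm) {
  stats::plogis((len_cm - 0.25) / 0.12)
}

#' Emit noisy pairwise calls from a truth set
#'
#' Converts ground-truth segments into the kind of call set a pairwise
#' IBD caller would produce: each true pairwise segment is detected with
#' probability `detect_fn(length)`, detected calls get jittered
#' endpoints and a LOD score increasing with length, and false calls
#' arrive as a Poisson process with short lengths and low LOD scores.
#' With detection below 1 the emitted set contains incomplete cliques —
#' exactly the situation graph conditioning exploits.
#'
#' @param truth an `ibd_truth` from [simulate_ibd_truth()].
#' @param detect_fn monotone non-decreasing function length(cM) ->
#'   detection probability (default [default_detection()]).
#' @param lod_true_fn function (length_cm, n) -> LOD draws for detected
#'   true calls; the default draws Normal(3 * len + 0.3, 0.5) truncated
#'   at 0.05.
#' @param lod_false_fn function (n) -> LOD draws for false calls; the
#'   default draws 0.1 + Exponential(mean 0.3).
#' @param false_per_mb expected false calls per Mb (default 0.2).
#' @param false_len_cm mean length of false calls in cM (default 0.15).
#' @param jitter_bp standard deviation of endpoint jitter (default
#'   2e4).
#' @param seed optional integer seed.
#' @return an [ibd_segments()] data.frame, valid input for
#'   [read_ibd_segments()] / [pigs_run()].
#' @export
emit_noisy_calls <- function(truth,
                             detect_fn = default_detection,
                             lod_true_fn = function(len_cm, n)
                               pmax(0.05, stats::rnorm(n, 3 * len_cm + 0.3,
                                                       0.5)),
                             lod_false_fn = function(n)
                               0.1 + stats::rexp(n, 1 / 0.3),
                             false_per_mb = 0.2, false_len_cm = 0.15,
                             jitter_bp = 2e4, seed = NULL) {
  stopifnot(inherits(truth, "ibd_truth"))
  if (!is.null(seed)) set.seed(seed)
  tr <- truth$segments
  L <- truth$params$chrom_length_bp
  chrom <- truth$params$chrom
  out <- list()
  if (nrow(tr)) {
    len <- segment_length_cm(tr)
    det <- detect_fn(len)
    hit <- stats::runif(nrow(tr)) < det
    if (any(hit)) {
      d <- tr[hit, , drop = FALSE]
      dlen <- len[hit]
      n <- nrow(d)
      start <- pmax(1, round(d$start_bp + stats::rnorm(n, 0, jitter_bp)))
      end <- pmin(L, round(d$end_bp + stats::rnorm(n, 0, jitter_bp)))
      bad <- start >= end
      start[bad] <- d$start_bp[bad]
      end[bad] <- d$end_bp[bad]
      d$start_bp <- start
      d$end_bp <- end
      d$lod <- lod_true_fn(dlen, n)
      d$prob <- NA_real_
      out[[length(out) + 1L]] <- d
    }
  }
  n_false <- stats::rpois(1L, false_per_mb * L / 1e6)
  if (n_false > 0) {
    haps <- sort_c(as.vector(outer(
      sprintf("S%04d", seq_len(ceiling(truth$params$n_haplotypes / 2))),
      1:2, hap_id)))[seq_len(truth$params$n_haplotypes)]
    rows <- lapply(seq_len(n_false), function(i) {
      pair <- sort_c(sample(haps, 2L))
      len_bp <- max(1e4, round(stats::rexp(1L, 1 / false_len_cm) * 1e6))
      start <- floor(stats::runif(1L, 1, max(2, L - len_bp)))
      ida <- parse_hap_id(pair[1L])
      idb <- parse_hap_id(pair[2L])
      data.frame(sample1 = ida$sample, hap1 = ida$hap_index,
                 sample2 = idb$sample, hap2 = idb$hap_index,
                 chrom = chrom, start_bp = start,
                 end_bp = min(L, start + len_bp - 1),
                 lod = lod_false_fn(1L), prob = NA_real_, inferred = FALSE,
                 stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- ibd_segments(do.call(rbind, rows))
  }
  if (!length(out))
    return(tr[0, , drop = FALSE])
  ibd_segments(do.call(rbind, lapply(out, function(d)
    d[ibd_cols_all()])))
}
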