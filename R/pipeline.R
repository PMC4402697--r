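#' Run the full IBD graph conditioning pipeline
#'
#' End-to-end driver: filter the pairwise calls, cut the genome into
#' breakpoint regions, build per-component probabilistic IBD graphs with
#' calibrated probabilities, condition every component's edges on the
#' whole component (exactly for 2-node components, by graph sampling
#' otherwise), lift the conditional probabilities back onto segments
#' (each original call takes the maximum estimate across the regions it
#' spans), emit newly inferred segments for previously uncalled pairs
#' that pass the probability threshold, merge overlapping same-pair
#' segments above the threshold, and filter the report by minimum
#' genetic length.
#'
#' @param segs an [ibd_segments()] data.frame (or a path readable by
#'   [read_ibd_segments()]).
#' @param map optional [genetic_map()]; without one, lengths assume
#'   1 cM/Mb.
#' @param min_lod,min_cm input call filters (defaults 0.1 / 0.1 cM).
#' @param calibration a [calibration_params()].
#' @param sampler a [sampler_config()]; its `seed` field is ignored here
#'   (use the `seed` argument, which seeds the whole run once).
#' @param weights a [weight_params()].
#' @param threshold probability threshold for emitting inferred segments
#'   and for merging (default 0.99).
#' @param min_report_cm minimum genetic length of reported segments
#'   (default 0.5 cM).
#' @param seed optional integer seeding the run; identical seeds give
#'   byte-identical results.
#' @return list of class `pigs_result`:
#'   * `segments`: the output [ibd_segments()] (originals with updated
#'     probabilities plus inferred segments, merged and length-filtered);
#'   * `components`: data.frame log with one row per sampled component
#'     (region, node count, iterations, convergence status);
#'   * `edge_probs`: data.frame of per-region conditional edge
#'     probabilities (`chrom`, `start_bp`, `end_bp` half-open,
#'     `hap_a`, `hap_b`, `called`, `p_input`, `p_hat`).
#' @examples
#' segs <- ibd_segments(data.frame(
#'   sample1 = c("A", "B"), hap1 = 1, sample2 = c("B", "C"), hap2 = 1,
#'   chrom = "1", start_bp = c(1e6, 1.2e6), end_bp = c(2e6, 2.1e6),
#'   lod = c(4, 4)))
#' res <- pigs_run(segs, seed = 1, min_report_cm = 0.1)
#' res$segments
#' @export
pigs_run <- function(segs, map = NULL, min_lod = 0.1, min_cm = 0.1,
                     calibration = calibration_params(),
                     sampler = sampler_config(),
                     weights = weight_params(),
                     threshold = 0.99, min_report_cm = 0.5, seed = NULL) {
  if (is.character(segs)) segs <- read_ibd_segments(segs)
  segs <- ibd_segments(segs)
  if (!is.null(seed)) set.seed(seed)
  sampler$seed <- NULL  # one seed for the whole run, set above
  segs <- filter_segments(segs, min_lod = min_lod, min_cm = min_cm,
                          map = map)
  regions <- build_region_graphs(segs, calib = calibration)

  seg_prob <- rep(NA_real_, nrow(segs))
  comp_log <- list()
  edge_log <- list()
  inferred <- list()
  for (region in regions) {
    p_hats <- vector("list", length(region$components))
    for (ci in seq_along(region$components)) {
      comp <- region$components[[ci]]
      G <- comp$graph
      n <- length(G$nodes)
      if (n == 2L) {
        # conditioning over two nodes is the identity: both configurations
        # are transitive and the ratio reduces to the input probability
        ph <- G$p
        iter <- 0L
        conv <- TRUE
        tout <- FALSE
      } else {
        fit <- run_sampler(G, sampler, weights)
        ph <- fit$p_hat
        iter <- fit$state$iterations
        conv <- fit$state$converged
        tout <- fit$state$timed_out
      }
      p_hats[[ci]] <- ph
      comp_log[[length(comp_log) + 1L]] <-
        data.frame(chrom = region$chrom, start_bp = region$start_bp,
                   end_bp = region$end_bp, nodes = n,
                   iterations = iter, converged = conv, timed_out = tout)
      up <- upper_pairs(n)
      edge_log[[length(edge_log) + 1L]] <-
        data.frame(chrom = region$chrom, start_bp = region$start_bp,
                   end_bp = region$end_bp,
                   hap_a = G$nodes[up$i], hap_b = G$nodes[up$j],
                   called = comp$called[cbind(up$i, up$j)],
                   p_input = G$p[cbind(up$i, up$j)],
                   p_hat = ph[cbind(up$i, up$j)],
                   stringsAsFactors = FALSE)
      # each member call takes the best estimate across its regions
      mem <- comp$segments
      for (r in mem) {
        i <- match(segs$hap_a[r], G$nodes)
        j <- match(segs$hap_b[r], G$nodes)
        seg_prob[r] <- max(seg_prob[r], ph[i, j], na.rm = TRUE)
      }
    }
    inf <- infer_new_segments(region, p_hats, segs, threshold = threshold)
    if (nrow(inf)) inferred[[length(inferred) + 1L]] <- inf
  }

  out <- segs
  out$prob <- seg_prob
  if (length(inferred)) {
    inferred <- do.call(rbind, inferred)
    # the same uncalled pair can pass the threshold in several adjacent
    # regions; merge those pieces before joining the originals
    inferred <- merge_inferred(inferred, threshold)
    out <- rbind(out[ibd_cols_all()], inferred[ibd_cols_all()])
  }
  out <- ibd_segments(out)
  out <- reconcile_overlaps(out, threshold)
  len <- segment_length_cm(out, map)
  out <- out[len >= min_report_cm, , drop = FALSE]
  rownames(out) <- NULL

  structure(list(segments = out,
                 components = if (length(comp_log))
                   do.call(rbind, comp_log) else NULL,
                 edge_probs = if (length(edge_log))
                   do.call(rbind, edge_log) else NULL),
            class = "pigs_result")
}

ibd_cols_all <- function() c("sample1", "hap1", "sample2", "hap2", "chrom",
                             "start_bp", "end_bp", "lod", "prob", "inferred")

merge_inferred <- function(inf, threshold) {
  pieces <- inf[c("hap_a", "hap_b", "chrom", "start_bp", "end_bp", "prob")]
  merged <- merge_across_regions(pieces, threshold = threshold)
  ids_a <- parse_hap_id(merged$hap_a)
  ids_b <- parse_hap_id(merged$hap_b)
  ibd_segments(data.frame(sample1 = ids_a$sample, hap1 = ids_a$hap_index,
                          sample2 = ids_b$sample, hap2 = ids_b$hap_index,
                          chrom = merged$chrom, start_bp = merged$start_bp,
                          end_bp = merged$end_bp, lod = NA_real_,
                          prob = merged$prob, inferred = TRUE,
                          stringsAsFactors = FALSE))
}

# merge overlapping/abutting same-pair segments when both pass the
# threshold; the merged segment keeps the maximum probability and the
# earliest LOD evidence, and counts as inferred only if all parts were
reconcile_overlaps <- function(segs, threshold) {
  key <- paste(segs$hap_a, segs$hap_b, segs$chrom, sep = "\r")
  parts <- split(seq_len(nrow(segs)), key)
  keep <- rep(TRUE, nrow(segs))
  for (idx in parts) {
    if (length(idx) < 2L) next
    idx <- idx[order(segs$start_bp[idx], segs$end_bp[idx])]
    cur <- idx[1L]
    for (r in idx[-1L]) {
      overlap <- segs$start_bp[r] <= segs$end_bp[cur] + 1
      both_pass <- !is.na(segs$prob[cur]) && !is.na(segs$prob[r]) &&
        segs$prob[cur] >= threshold && segs$prob[r] >= threshold
      if (overlap && both_pass) {
        segs$end_bp[cur] <- max(segs$end_bp[cur], segs$end_bp[r])
        segs$prob[cur] <- max(segs$prob[cur], segs$prob[r])
        segs$lod[cur] <- if (is.na(segs$lod[cur])) segs$lod[r]
          else max(segs$lod[cur], segs$lod[r], na.rm = TRUE)
        segs$inferred[cur] <- segs$inferred[cur] && segs$inferred[r]
        keep[r] <- FALSE
      } else {
        cur <- r
      }
    }
  }
  out <- segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pigs_result <- function(x, ...) {
  n_inf <- sum(x$segments$inferred)
  cat("IBD graph conditioning result:", nrow(x$segments), "segments (",
      n_inf, "inferred ),",
      if (!is.null(x$components)) nrow(x$components) else 0,
      "sampled components\n")
  invisible(x)
}
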