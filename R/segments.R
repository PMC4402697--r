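#' IBD segment tables
#'
#' Pairwise IBD segment calls are kept in a plain data.frame with one row
#' per call and columns `sample1`, `hap1`, `sample2`, `hap2`, `chrom`,
#' `start_bp`, `end_bp` (1-based inclusive base-pair coordinates, as in
#' the Refined IBD / Beagle `.ibd` dialect), `lod`, `prob` and
#' `inferred`. `ibd_segments()` validates and canonicalises such a table:
#' the haplotype pair is oriented so the first haplotype id sorts before
#' the second, coordinates are checked, and at least one of `lod` /
#' `prob` must be present per row.
#'
#' @param df data.frame with at least `sample1`, `hap1`, `sample2`,
#'   `hap2`, `chrom`, `start_bp`, `end_bp` and one of `lod` / `prob`.
#' @return canonicalised data.frame of class `ibd_segments`, with
#'   derived columns `hap_a` and `hap_b` (canonically ordered haplotype
#'   ids).
#' @export
ibd_segments <- function(df) {
  req <- c("sample1", "hap1", "sample2", "hap2", "chrom", "start_bp",
           "end_bp")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$lod)) df[["lod"]] <- rep(NA_real_, nrow(df))
  if (is.null(df$prob)) df[["prob"]] <- rep(NA_real_, nrow(df))
  if (is.null(df$inferred)) df[["inferred"]] <- rep(FALSE, nrow(df))
  df$chrom <- as.character(df$chrom)
  df$start_bp <- as.numeric(df$start_bp)
  df$end_bp <- as.numeric(df$end_bp)
  if (any(is.na(df$start_bp) | is.na(df$end_bp)))
    stop("non-numeric coordinates")
  if (any(df$start_bp > df$end_bp))
    stop("start_bp must not exceed end_bp")
  if (any(is.na(df$lod) & is.na(df$prob)))
    stop("every segment needs a LOD score or a probability")
  ha <- hap_id(df$sample1, df$hap1)
  hb <- hap_id(df$sample2, df$hap2)
  if (any(ha == hb)) stop("a segment cannot pair a haplotype with itself")
  u <- sort_c(unique(c(ha, hb)))
  swap <- match(ha, u) > match(hb, u)
  if (any(swap)) {
    tmp <- df[swap, c("sample1", "hap1")]
    df[swap, c("sample1", "hap1")] <- df[swap, c("sample2", "hap2")]
    df[swap, c("sample2", "hap2")] <- tmp
    t2 <- ha[swap]
    ha[swap] <- hb[swap]
    hb[swap] <- t2
  }
  df$hap_a <- ha
  df$hap_b <- hb
  rownames(df) <- NULL
  class(df) <- c("ibd_segments", "data.frame")
  df
}

ibd_cols <- c("sample1", "hap1", "sample2", "hap2", "chrom", "start_bp",
              "end_bp", "lod", "prob", "inferred")

#' Read pairwise IBD segment calls
#'
#' Reads tab-delimited segment files in the Refined IBD / Beagle `.ibd`
#' dialect: columns sample1, haplotype-index1, sample2,
#' haplotype-index2, chromosome, start bp, end bp, LOD score. Files
#' written by [write_ibd_segments()] carry two extra columns
#' (probability, inferred flag) and a `#`-prefixed header, both handled
#' transparently. Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @return an [ibd_segments()] data.frame.
#' @export
read_ibd_segments <- function(path) {
  if (!file.exists(path)) stop("cannot open '", path, "': no such file")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("no segment rows in ", path)
    return(ibd_segments(data.frame(sample1 = character(0), hap1 = integer(0),
                                   sample2 = character(0), hap2 = integer(0),
                                   chrom = character(0),
                                   start_bp = numeric(0),
                                   end_bp = numeric(0), lod = numeric(0))))
  }
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(rows)
  if (!all(nf %in% c(8L, 10L)))
    stop("unexpected column count (", paste(unique(nf[!nf %in% c(8L, 10L)]),
                                            collapse = "/"),
         ") on line(s) ",
         paste(utils::head(lineno[!nf %in% c(8L, 10L)], 5L), collapse = ", "))
  if (length(unique(nf)) > 1L)
    stop("mixed column counts in ", path)
  mat <- do.call(rbind, rows)
  df <- data.frame(sample1 = mat[, 1L], hap1 = as.integer(mat[, 2L]),
                   sample2 = mat[, 3L], hap2 = as.integer(mat[, 4L]),
                   chrom = mat[, 5L],
                   start_bp = suppressWarnings(as.numeric(mat[, 6L])),
                   end_bp = suppressWarnings(as.numeric(mat[, 7L])),
                   lod = suppressWarnings(as.numeric(mat[, 8L])),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start_bp) | is.na(df$end_bp))
  if (length(bad))
    stop("non-numeric coordinates on line(s) ",
         paste(utils::head(lineno[bad], 5L), collapse = ", "))
  if (nf[1L] == 10L) {
    df$prob <- suppressWarnings(as.numeric(mat[, 9L]))
    df$prob[mat[, 9L] %in% c("NA", ".")] <- NA_real_
    df$inferred <- mat[, 10L] %in% c("1", "TRUE", "true")
  }
  ibd_segments(df)
}

#' Write IBD segments
#'
#' Emits the input `.ibd` dialect plus a probability column (6 decimal
#' places) and an inferred flag, with a `#`-prefixed header line. Files
#' round-trip through [read_ibd_segments()].
#'
#' @param segs an [ibd_segments()] data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ibd_segments <- function(segs, path) {
  segs <- ibd_segments(segs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(ibd_cols, collapse = "\t")), con)
  if (nrow(segs)) {
    out <- data.frame(segs$sample1, segs$hap1, segs$sample2, segs$hap2,
                      segs$chrom,
                      format(segs$start_bp, scientific = FALSE, trim = TRUE),
                      format(segs$end_bp, scientific = FALSE, trim = TRUE),
                      ifelse(is.na(segs$lod), "NA",
                             format(segs$lod, trim = TRUE)),
                      ifelse(is.na(segs$prob), "NA",
                             sprintf("%.6f", segs$prob)),
                      as.integer(segs$inferred))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Genetic maps and centimorgan interpolation
#'
#' Reads a genetic map as either a three-column table (chromosome, bp
#' position, cM position) or a PLINK `.map` file (chromosome, id, cM,
#' bp). Positions must be strictly increasing in bp and non-decreasing
#' in cM within each chromosome.
#'
#' @param path file path.
#' @return a `genetic_map` object: named list of per-chromosome
#'   data.frames with columns `bp` and `cm`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) == 3L) {
    df <- data.frame(chrom = as.character(tab[[1L]]),
                     bp = as.numeric(tab[[2L]]), cm = as.numeric(tab[[3L]]))
  } else if (ncol(tab) == 4L) {
    df <- data.frame(chrom = as.character(tab[[1L]]),
                     bp = as.numeric(tab[[4L]]), cm = as.numeric(tab[[3L]]))
  } else {
    stop("genetic map must have 3 (chrom, bp, cM) or 4 (PLINK .map) columns")
  }
  genetic_map(df)
}

#' @rdname read_genetic_map
#' @param df data.frame with columns `chrom`, `bp`, `cm`.
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("chrom", "bp", "cm") %in% names(df)))
  out <- lapply(split(df[c("bp", "cm")], df$chrom), function(d) {
    d <- d[order(d$bp), , drop = FALSE]
    if (any(diff(d$bp) <= 0)) stop("bp positions must be strictly increasing")
    if (any(diff(d$cm) < 0)) stop("cM positions must be non-decreasing")
    d
  })
  structure(out, class = "genetic_map")
}

#' @rdname read_genetic_map
#' @param map a `genetic_map`, or `NULL` for the constant 1 cM/Mb
#'   default (matching a uniform recombination rate of 1e-8 per bp).
#' @param chrom chromosome label(s).
#' @param bp base-pair position(s).
#' @return `cm_at()`: numeric vector of interpolated cM positions
#'   (linear inside the map, constant extension outside).
#' @export
cm_at <- function(map, chrom, bp) {
  if (is.null(map)) return(bp / 1e6)
  chrom <- rep_len(as.character(chrom), length(bp))
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    d <- map[[ch]]
    if (is.null(d)) stop("chromosome ", ch, " not in genetic map")
    out[sel] <- stats::approx(d$bp, d$cm, xout = bp[sel], rule = 2,
                              ties = "ordered")$y
  }
  out
}

#' Centimorgan length of segments
#'
#' @param segs an [ibd_segments()] data.frame.
#' @inheritParams cm_at
#' @return numeric vector of segment lengths in cM.
#' @export
segment_length_cm <- function(segs, map = NULL) {
  cm_at(map, segs$chrom, segs$end_bp) - cm_at(map, segs$chrom, segs$start_bp)
}

#' Filter segment calls
#'
#' Keeps segments passing a LOD threshold (default 0.1; rows without a
#' LOD, e.g. inferred segments, are exempt) and a minimum genetic length
#' (default 0.1 cM).
#'
#' @param segs an [ibd_segments()] data.frame.
#' @param min_lod minimum LOD score.
#' @param min_cm minimum genetic length in cM.
#' @param map optional genetic map (see [cm_at()]).
#' @return filtered [ibd_segments()] data.frame.
#' @export
filter_segments <- function(segs, min_lod = 0.1, min_cm = 0.1, map = NULL) {
  segs <- ibd_segments(segs)
  len <- segment_length_cm(segs, map)
  keep <- (is.na(segs$lod) | segs$lod >= min_lod) & len >= min_cm
  out <- segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Breakpoints of a segment set
#'
#' The IBD graph only changes where some input segment begins or ends,
#' so those positions are the only ones worth analysing. Returns, per
#' chromosome, the sorted unique set of all segment starts and ends+1;
#' consecutive breakpoints delimit the half-open analysis intervals
#' `[b_k, b_k+1)` over which the graph is constant.
#'
#' @param segs an [ibd_segments()] data.frame.
#' @return named list (by chromosome) of sorted numeric breakpoint
#'   vectors.
#' @export
ibd_breakpoints <- function(segs) {
  segs <- ibd_segments(segs)
  if (!nrow(segs)) return(structure(list(), names = character(0)))
  lapply(split(segs, segs$chrom), function(d)
    sort(unique(c(d$start_bp, d$end_bp + 1))))
}

#' Build per-region probabilistic IBD graphs
#'
#' Cuts the genome at the breakpoints of the (already filtered) call
#' set, and for every analysis interval builds the probabilistic IBD
#' graph over the haplotypes incident to a covering segment: called
#' pairs receive their calibrated LOD probability, and pairs inside the
#' same connected component that were never called receive the prior
#' `epsilon`. Disjoint components are returned as separate sampling
#' problems because they cannot influence each other's conditional
#' probabilities.
#'
#' @param segs filtered [ibd_segments()] data.frame.
#' @param calib a [calibration_params()].
#' @param node_cap components larger than this are still processed but
#'   flagged with a message (default 200).
#' @return list of `analysis_region` objects, each a list with `chrom`,
#'   `start_bp`, `end_bp` (half-open interval) and `components`, a list
#'   of lists with elements `graph` ([ibd_graph()]), `called` (logical
#'   matrix marking pairs backed by a call) and `segments` (row indices
#'   of the member segments in `segs`).
#' @export
build_region_graphs <- function(segs, calib = calibration_params(),
                                node_cap = 200L) {
  segs <- ibd_segments(segs)
  regions <- list()
  if (!nrow(segs)) return(regions)
  bps <- ibd_breakpoints(segs)
  for (ch in names(bps)) {
    b <- bps[[ch]]
    csegs_idx <- which(segs$chrom == ch)
    csegs <- segs[csegs_idx, , drop = FALSE]
    for (k in seq_len(length(b) - 1L)) {
      lo <- b[k]
      hi <- b[k + 1L]
      cover <- csegs$start_bp <= lo & csegs$end_bp + 1 >= hi
      if (!any(cover)) next
      member_idx <- csegs_idx[cover]
      mem <- segs[member_idx, , drop = FALSE]
      nodes <- sort_c(unique(c(mem$hap_a, mem$hap_b)))
      n <- length(nodes)
      # calibrated probability per called pair; several covering calls for
      # the same pair keep the strongest evidence; rows carrying a
      # probability instead of a LOD (e.g. previously inferred) use it
      pcall <- ifelse(!is.na(mem$lod),
                      lod_to_probability(mem$lod, calib),
                      ifelse(!is.na(mem$prob), mem$prob, calib$epsilon))
      pcall <- pmin(pmax(pcall, calib$p_min), calib$p_max)
      adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
      pmat <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
      for (r in seq_len(nrow(mem))) {
        a <- mem$hap_a[r]
        bnode <- mem$hap_b[r]
        adj[a, bnode] <- adj[bnode, a] <- TRUE
        pmat[a, bnode] <- pmat[bnode, a] <-
          max(pmat[a, bnode], pcall[r], na.rm = TRUE)
      }
      memb <- component_membership(adj)
      comps <- list()
      for (cc in unique(memb)) {
        sel <- which(memb == cc)
        if (length(sel) > node_cap)
          message("component with ", length(sel), " nodes (cap ", node_cap,
                  ") in region ", ch, ":", lo, "-", hi,
                  "; processing anyway")
        sub_p <- pmat[sel, sel, drop = FALSE]
        sub_called <- adj[sel, sel, drop = FALSE]
        sub_p[!sub_called] <- calib$epsilon
        seg_rows <- member_idx[mem$hap_a %in% nodes[sel]]
        comps[[length(comps) + 1L]] <- list(
          graph = ibd_graph(sub_p, nodes = nodes[sel],
                            region = list(chrom = ch, start_bp = lo,
                                          end_bp = hi)),
          called = sub_called,
          segments = seg_rows)
      }
      regions[[length(regions) + 1L]] <-
        structure(list(chrom = ch, start_bp = lo, end_bp = hi,
                       components = comps),
                  class = "analysis_region")
    }
  }
  regions
}

#' Merge per-region probabilities into segments
#'
#' The same haplotype pair can be assigned (slightly different)
#' probabilities in several adjacent analysis intervals. Pieces on the
#' same pair and chromosome whose probabilities pass the threshold are
#' merged into one segment spanning their union whenever they overlap or
#' abut, and the merged segment takes the maximum probability of its
#' parts. Sub-threshold pieces are emitted unmerged.
#'
#' @param pieces data.frame with columns `hap_a`, `hap_b`, `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive) and `prob`.
#' @param threshold merge threshold (default 0.99).
#' @return data.frame of the same shape, merged.
#' @export
merge_across_regions <- function(pieces, threshold = 0.99) {
  if (!nrow(pieces)) return(pieces)
  key <- paste(pieces$hap_a, pieces$hap_b, pieces$chrom, sep = "\r")
  out <- lapply(split(pieces, key), function(d) {
    d <- d[order(d$start_bp, d$end_bp), , drop = FALSE]
    pass <- d$prob >= threshold
    res <- d[0, , drop = FALSE]
    run <- NULL
    flush <- function(run, res) if (is.null(run)) res else rbind(res, run)
    for (r in seq_len(nrow(d))) {
      row <- d[r, , drop = FALSE]
      if (!pass[r]) {
        res <- flush(run, res)
        run <- NULL
        res <- rbind(res, row)
      } else if (!is.null(run) && row$start_bp <= run$end_bp + 1) {
        run$end_bp <- max(run$end_bp, row$end_bp)
        run$prob <- max(run$prob, row$prob)
      } else {
        res <- flush(run, res)
        run <- row
      }
    }
    res <- flush(run, res)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$hap_a, out$hap_b, out$start_bp), , drop = FALSE]
}

#' Infer segments for previously uncalled pairs
#'
#' After conditioning, an uncalled pair inside a component can come out
#' with a high conditional probability. Such pairs are emitted as new
#' segments whose interval is the intersection of all member-segment
#' intervals of the component: without looking at sequence, IBD can only
#' be asserted somewhere every supporting segment exists.
#'
#' @param region an `analysis_region` from [build_region_graphs()].
#' @param p_hats list of estimate matrices (one per component of the
#'   region, as returned in `p_hat` by [run_sampler()]).
#' @param segs the [ibd_segments()] the region was built from.
#' @param threshold minimum conditional probability (default 0.99).
#' @return [ibd_segments()] data.frame of inferred segments (possibly
#'   empty), `inferred = TRUE`, `prob` set, no LOD.
#' @export
infer_new_segments <- function(region, p_hats, segs, threshold = 0.99) {
  out <- list()
  for (ci in seq_along(region$components)) {
    comp <- region$components[[ci]]
    ph <- p_hats[[ci]]
    nodes <- comp$graph$nodes
    n <- length(nodes)
    if (n < 3L) next
    mem <- segs[comp$segments, , drop = FALSE]
    lo <- max(mem$start_bp)
    hi <- min(mem$end_bp)
    stopifnot(lo <= hi)  # members all cover the analysis interval
    up <- upper_pairs(n)
    for (k in seq_along(up$i)) {
      i <- up$i[k]
      j <- up$j[k]
      if (comp$called[i, j]) next
      p <- ph[nodes[i], nodes[j]]
      if (is.na(p) || p < threshold) next
      ida <- parse_hap_id(nodes[i])
      idb <- parse_hap_id(nodes[j])
      out[[length(out) + 1L]] <-
        data.frame(sample1 = ida$sample, hap1 = ida$hap_index,
                   sample2 = idb$sample, hap2 = idb$hap_index,
                   chrom = region$chrom, start_bp = lo, end_bp = hi,
                   lod = NA_real_, prob = p, inferred = TRUE,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(ibd_segments(data.frame(sample1 = character(0), hap1 = integer(0),
                                   sample2 = character(0), hap2 = integer(0),
                                   chrom = character(0),
                                   start_bp = numeric(0),
                                   end_bp = numeric(0), lod = numeric(0),
                                   prob = numeric(0), inferred = logical(0))))
  ibd_segments(do.call(rbind, out))
}
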