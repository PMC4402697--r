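#' Calibration parameters for LOD-to-probability conversion
#'
#' Pairwise IBD callers in the Refined IBD / Beagle family report a LOD
#' score: the base-10 log likelihood ratio of one shared haplotype versus
#' none. Downstream graph conditioning needs probabilities. The
#' conversion is anchored on the genome-wide prior probability that a
#' random haplotype pair is IBD at a random locus, `epsilon` (default
#' 0.0046, the average proportion of the genome shared IBD between sample
#' pairs in a European-like population). Uncalled pairs receive exactly
#' this prior, never 0, so every graph configuration keeps positive
#' probability and every edge remains sampleable.
#'
#' @param epsilon prior probability of IBD for a random pair at a random
#'   locus; also the probability assigned to uncalled edges.
#' @param p_min lower clamp for converted probabilities (default
#'   `epsilon`).
#' @param p_max upper clamp (default 0.999); keeps probabilities away
#'   from 1 so configuration probabilities stay finite in log space,
#'   while still above the sampler's 0.99 pinning threshold.
#' @param mode `"fitted_curve"` (default): the empirically fitted
#'   LOD-to-true-positive-rate curve `p = (2o + af) / (o + f)`;
#'   `"plain_odds"`: the textbook Bayes posterior `o / (1 + o)`;
#'   `"empirical"`: a function fitted from labelled data with
#'   [fit_empirical_calibration()].
#' @param empirical_fn optional function (lod -> probability) used when
#'   `mode = "empirical"`.
#' @return list with class `calibration_params`.
#' @export
calibration_params <- function(epsilon = 0.0046,
                               p_min = epsilon,
                               p_max = 0.999,
                               mode = c("fitted_curve", "plain_odds",
                                        "empirical"),
                               empirical_fn = NULL) {
  stopifnot(epsilon > 0, epsilon < p_max, p_max < 1, p_min >= 0,
            p_min <= p_max)
  structure(list(epsilon = epsilon, p_min = p_min, p_max = p_max,
                 mode = match.arg(mode), empirical_fn = empirical_fn),
            class = "calibration_params")
}

#' Convert LOD scores to IBD probabilities
#'
#' In `"fitted_curve"` mode the conversion follows the curve fitted to
#' the observed relationship between LOD score and true positive rate of
#' IBD segments: with prior odds `O = epsilon / (1 - epsilon)`, posterior
#' odds `o = O * 10^lod` (Bayes rule for odds with a base-10 likelihood
#' ratio), `f = epsilon * 10^3 / 0.997 - epsilon * 10^3`, and a shape
#' term `a = (1 - lod)^3 / 7` for `lod <= 1` and `-0.15` above, the raw
#' value is `p = (2o + a f) / (o + f)`. The raw curve exceeds 1 for large
#' LOD, so results are clamped into `[p_min, p_max]`. `"plain_odds"` mode
#' returns the clamped textbook posterior `o / (1 + o)`. `"empirical"`
#' mode delegates to the function stored in the parameters.
#'
#' `NA` LOD scores denote uncalled edges and map to the prior `epsilon`.
#'
#' @param lod numeric vector of LOD scores (finite or `NA`).
#' @param params a [calibration_params()].
#' @return numeric vector of probabilities in `[p_min, p_max]`, never
#'   exactly 0 or 1.
#' @examples
#' lod_to_probability(0.1)  # ~0.665
#' lod_to_probability(NA)   # the prior, 0.0046
#' @export
lod_to_probability <- function(lod, params = calibration_params()) {
  if (any(is.infinite(lod))) stop("LOD scores must be finite or NA")
  eps <- params$epsilon
  out <- rep(eps, length(lod))
  ok <- !is.na(lod)
  if (any(ok)) {
    l <- lod[ok]
    prior_odds <- eps / (1 - eps)
    o <- prior_odds * 10^l
    p <- switch(params$mode,
      fitted_curve = {
        f <- eps * 1e3 / 0.997 - eps * 1e3
        a <- ifelse(l <= 1, (1 - l)^3 / 7, -0.15)
        (2 * o + a * f) / (o + f)
      },
      plain_odds = o / (1 + o),
      empirical = {
        if (is.null(params$empirical_fn))
          stop("empirical mode needs an empirical_fn; see ",
               "fit_empirical_calibration()")
        params$empirical_fn(l)
      })
    out[ok] <- pmin(pmax(p, params$p_min), params$p_max)
  }
  out
}

#' Fit an empirical LOD-to-probability calibration
#'
#' Bins labelled calls by LOD score, computes the true-positive fraction
#' per bin, enforces monotonicity by isotonic regression
#' (pool-adjacent-violators via [stats::isoreg()]), and returns a
#' non-decreasing interpolated conversion function clamped to
#' `[p_min, p_max]`. Bins are quantile-based so each holds roughly the
#' same number of calls, which makes the unweighted isotonic fit
#' appropriate.
#'
#' Intended for recalibration when the study population's demography
#' differs from the one behind the default fitted curve.
#'
#' @param lod numeric vector of LOD scores of labelled calls.
#' @param is_true logical (or 0/1) vector: did the call overlap a true
#'   IBD segment?
#' @param bins number of LOD bins (default 10; at least 2 non-empty bins
#'   are required).
#' @param params a [calibration_params()] supplying the clamping bounds.
#' @return a function mapping LOD score vectors to probabilities;
#'   non-decreasing, range within `[p_min, p_max]`.
#' @export
fit_empirical_calibration <- function(lod, is_true, bins = 10L,
                                      params = calibration_params()) {
  if (!length(lod)) stop("no labelled calls supplied")
  if (length(lod) != length(is_true))
    stop("lod and is_true must have the same length")
  is_true <- as.logical(is_true)
  brk <- unique(stats::quantile(lod, probs = seq(0, 1, length.out = bins + 1),
                                names = FALSE))
  if (length(brk) < 3L)
    stop("need at least 2 distinct LOD bins; got ", length(brk) - 1L)
  bin <- cut(lod, breaks = brk, include.lowest = TRUE)
  centers <- tapply(lod, bin, mean)
  fracs <- tapply(is_true, bin, mean)
  keep <- !is.na(fracs)
  if (sum(keep) < 2L) stop("need at least 2 non-empty LOD bins")
  centers <- as.numeric(centers[keep])
  fracs <- as.numeric(fracs[keep])
  ord <- order(centers)
  centers <- centers[ord]
  fracs <- fracs[ord]
  iso <- stats::isoreg(centers, fracs)
  yf <- pmin(pmax(iso$yf, params$p_min), params$p_max)
  fn <- stats::approxfun(centers, yf, rule = 2, ties = "ordered")
  function(l) pmin(pmax(fn(l), params$p_min), params$p_max)
}
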