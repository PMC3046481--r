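# Synthetic-track generator: produces tracks of every genomic type with
# controlled dependence structure, for null-model calibration, oracle
# testing, and the demonstration that over-simple null models declare
# independent autocorrelated tracks associated.  Same parameters + seed
# give a bit-identical track.

region_list <- function(chrom, start, end) {
  list(chrom = chrom, start = start, end = end)
}

#' Simulate a Poisson point track
#'
#' Draws a Poisson number of points (mean `rate` per bp, or the total of
#' the supplied intensity) and places them without replacement, uniformly
#' or with probability proportional to the intensity -- i.e. a
#' (non-)homogeneous Poisson process discretized to distinct bp.
#'
#' @param region list with `chrom`, `start`, `end` (0-based half-open).
#' @param rate expected points per bp (homogeneous case).
#' @param intensity an `IntensityTrack` (overrides `rate`).
#' @param seed optional integer seed.
#' @return a `PointTrack`.
#' @export
sim_points <- function(region, rate = NULL, intensity = NULL,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- region$end - region$start
  pos <- seq.int(region$start, region$end - 1)
  if (!is.null(intensity)) {
    v <- intensity$values[[region$chrom]]
    lam <- rep(0, len)
    ok <- pos < length(v)
    lam[ok] <- v[pos[ok] + 1]
    lam[is.na(lam)] <- 0
    total <- sum(lam)
    if (total <= 0) stop("intensity sums to zero on the region")
    n <- stats::rpois(1L, total)
    n <- min(n, sum(lam > 0))
    draw <- if (n > 0L) sort(pos[lam > 0][sample.int(sum(lam > 0), n,
                                                     prob = lam[lam > 0])])
            else numeric()
  } else {
    if (is.null(rate) || rate <= 0) stop("need rate > 0 or an intensity")
    n <- min(stats::rpois(1L, rate * len), len)
    draw <- if (n > 0L) sort(pos[sample.int(len, n)]) else numeric()
  }
  point_track(setNames(list(draw), region$chrom))
}

draw_lengths <- function(dist, n) {
  if (dist$dist == "fixed") return(rep(as.numeric(dist$value), n))
  if (dist$dist == "geom") {
    if (dist$mean < 1) stop("geometric mean length must be >= 1")
    return(stats::rgeom(n, 1 / dist$mean) + 1)
  }
  if (dist$dist == "empirical") return(sample(dist$values, n,
                                              replace = TRUE))
  stop("unknown length distribution: ", dist$dist)
}

#' Simulate a segment track by alternating gap/segment draws
#'
#' Gap and segment lengths are drawn alternately from the given
#' distributions (geometric with a given mean, fixed, or empirical) until
#' the region is exhausted; the last segment is truncated at the region
#' end.  Geometric (memoryless) lengths are the default family.
#'
#' @param region list with `chrom`, `start`, `end`.
#' @param length_dist,gap_dist distribution spec: `list(dist = "geom",
#'   mean = )`, `list(dist = "fixed", value = )`, or `list(dist =
#'   "empirical", values = )`.
#' @param seed optional integer seed.
#' @return a `SegmentTrack` (disjoint, sorted).
#' @export
sim_segments <- function(region,
                         length_dist = list(dist = "geom", mean = 100),
                         gap_dist = list(dist = "geom", mean = 100),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  end <- region$end
  pos <- region$start
  starts <- numeric(); ends <- numeric()
  repeat {
    pos <- pos + draw_lengths(gap_dist, 1L)
    if (pos >= end) break
    len <- draw_lengths(length_dist, 1L)
    starts <- c(starts, pos)
    ends <- c(ends, min(pos + len, end))
    pos <- pos + len
    if (pos >= end) break
  }
  new_track(list(segments = setNames(
    list(cbind(start = starts, end = ends)), region$chrom)),
    "SegmentTrack")
}

#' Simulate autocorrelated coverage by a two-state Markov chain
#'
#' A per-bp chain with `P(covered -> covered) = p_stay` and
#' `P(uncovered -> covered) = p_enter`; covered runs are returned as
#' segments.  Covered run lengths are geometric with mean
#' `1 / (1 - p_stay)`; stationary coverage is
#' `p_enter / (p_enter + 1 - p_stay)`.  The chain starts from its
#' stationary distribution.  With `p_stay = p_enter` the chain degenerates
#' to iid Bernoulli coverage.  This is the generator of the autocorrelated
#' tracks whose pairwise overlap looks significant under over-simple
#' per-bp null models.
#'
#' @param region list with `chrom`, `start`, `end`.
#' @param p_enter,p_stay transition probabilities in (0, 1).
#' @param seed optional integer seed.
#' @return a `SegmentTrack`.
#' @export
sim_markov_coverage <- function(region, p_enter, p_stay, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(p_enter, p_stay) <= 0) || any(c(p_enter, p_stay) >= 1))
    stop("p_enter and p_stay must lie in (0, 1)")
  len <- region$end - region$start
  pi1 <- p_enter / (p_enter + 1 - p_stay)
  state <- stats::runif(1L) < pi1
  pos <- 0
  starts <- numeric(); ends <- numeric()
  while (pos < len) {
    run <- if (state) stats::rgeom(1L, 1 - p_stay) + 1
           else stats::rgeom(1L, p_enter) + 1
    run <- min(run, len - pos)
    if (state) {
      starts <- c(starts, region$start + pos)
      ends <- c(ends, region$start + pos + run)
    }
    pos <- pos + run
    state <- !state
  }
  new_track(list(segments = setNames(
    list(cbind(start = starts, end = ends)), region$chrom)),
    "SegmentTrack")
}

#' Simulate a smooth function track
#'
#' A circular moving average (window `window`) of iid Gaussian noise,
#' giving an autocorrelated per-bp function; lag-1 autocorrelation grows
#' with the window.  With `gc_like = TRUE` the smooth latent is
#' thresholded at the `1 - gc_fraction` quantile into a 0/1 indicator,
#' mimicking runs of base composition.
#'
#' @param region list with `chrom`, `start`, `end`.
#' @param window moving-average window in bp (1 = iid noise).
#' @param noise_sd standard deviation of the underlying noise.
#' @param gc_like return a 0/1 indicator instead of the smooth values.
#' @param gc_fraction fraction of 1s for `gc_like` (default 0.5).
#' @param seed optional integer seed.
#' @return a `FunctionTrack` defined exactly on the region.
#' @export
sim_function <- function(region, window = 1L, noise_sd = 1,
                         gc_like = FALSE, gc_fraction = 0.5,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (window < 1L) stop("window must be >= 1")
  len <- region$end - region$start
  z <- stats::rnorm(len, sd = noise_sd)
  v <- if (window > 1L)
    as.numeric(stats::filter(z, rep(1 / window, window), sides = 2L,
                             circular = TRUE))
  else z
  if (gc_like)
    v <- as.numeric(v > stats::quantile(v, 1 - gc_fraction))
  out <- rep(NA_real_, region$end)
  out[(region$start + 1):region$end] <- v
  function_track(setNames(list(out), region$chrom))
}

#' Attach simulated marks to a point or segment track
#'
#' Marks are drawn per element, either independently from a normal
#' distribution or as a linear function of a supplied per-element
#' covariate plus Gaussian noise (`mark = intercept + slope * covariate +
#' N(0, noise_sd)`), which ties marks to e.g. local point counts with a
#' known effect size for power studies.
#'
#' @param base a `PointTrack` or `SegmentTrack` (nonempty).
#' @param model `list(model = "independent", mean = , sd = )` or
#'   `list(model = "linear", covariate = , slope = , intercept = ,
#'   noise_sd = )`; `covariate` is one numeric value per element, in
#'   track order.
#' @param seed optional integer seed.
#' @return a `MarkedPointTrack` or `MarkedSegmentTrack`.
#' @export
sim_marked <- function(base, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- track_counts(base)
  n <- sum(counts)
  if (n == 0L) stop("base track is empty")
  marks <- if (model$model == "independent") {
    stats::rnorm(n, mean = model$mean %||% 0, sd = model$sd %||% 1)
  } else if (model$model == "linear") {
    cov <- model$covariate
    if (length(cov) != n) stop("covariate must have one value per element")
    (model$intercept %||% 0) + model$slope * cov +
      stats::rnorm(n, sd = model$noise_sd %||% 1)
  } else stop("unknown mark model: ", model$model)
  idx <- split(seq_len(n), factor(rep(names(counts), counts),
                                  levels = names(counts)))
  mark_list <- lapply(setNames(names(counts), names(counts)),
                      function(ch) marks[idx[[ch]]])
  if (infer_type(base) == "UP")
    marked_point_track(base$positions, mark_list)
  else
    marked_segment_track(base$segments, mark_list)
}
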