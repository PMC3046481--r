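# Descriptive test statistics on clipped tracks.  All functions return a
# bare numeric (NA_real_ when undefined on the given data); effect sizes
# are derived by the inference layer.  Each statistic has a per-bp /
# per-element brute-force oracle in the test suite.

pooled_positions <- function(track) {
  unlist(track$positions, use.names = FALSE)
}

pooled_segments <- function(track) {
  do.call(rbind, c(unname(track$segments),
                   list(as_segment_matrix(NULL))))
}

segments_to_iranges <- function(m) {
  IRanges::IRanges(start = as.integer(m[, 1L]) + 1L,
                   end = as.integer(m[, 2L]))
}

#' Base-pair overlap between two segment tracks
#'
#' Total number of base pairs covered by both tracks, summed over the
#' chromosomes they share.
#'
#' @param a,b `SegmentTrack`s (clipped to the analysis region).
#' @return total overlap in bp.
#' @examples
#' a <- segment_track(list(chrT = cbind(0, 10)))
#' b <- segment_track(list(chrT = cbind(5, 15)))
#' bp_overlap(a, b)  # 5
#' @export
bp_overlap <- function(a, b) {
  chroms <- intersect(track_chroms(a), track_chroms(b))
  total <- 0
  for (ch in chroms)
    total <- total + overlap_one(a$segments[[ch]], b$segments[[ch]])
  total
}

# overlap of two disjoint sorted interval sets; W(x) = covered bp of b
# below x, so each a-interval [s,e) contributes W(e) - W(s)
overlap_one <- function(a, b) {
  if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) return(0)
  bs <- b[, 1L]; be <- b[, 2L]
  cum <- c(0, cumsum(be - bs))
  W <- function(x) {
    i <- findInterval(x, bs)
    overshoot <- numeric(length(x))
    started <- i >= 1L
    overshoot[started] <- pmax(0, be[i[started]] - x[started])
    cum[i + 1L] - overshoot
  }
  sum(W(a[, 2L]) - W(a[, 1L]))
}

#' Count points falling inside segments
#'
#' Number of points `p` with some segment `[s, e)` such that
#' `s <= p < e` (half-open: a point at a segment's `end` is outside).
#'
#' @param points a `PointTrack`.
#' @param segs a `SegmentTrack` (disjoint, sorted).
#' @return integer count.
#' @export
points_in_segments <- function(points, segs) {
  total <- 0L
  for (ch in track_chroms(points)) {
    p <- points$positions[[ch]]
    m <- segs$segments[[ch]]
    if (is.null(m) || !nrow(m) || !length(p)) next
    idx <- findInterval(p, m[, 1L])
    inside <- idx > 0
    inside[inside] <- p[inside] < m[idx[inside], 2L]
    total <- total + sum(inside)
  }
  total
}

#' Fraction of a region covered by segments
#'
#' Covered bp divided by the region's defined length (mask-aware).
#'
#' @param segs a `SegmentTrack` clipped to the region.
#' @param region list with `chrom`, `start`, `end` (0-based half-open).
#' @param genome a [genome_context()].
#' @return fraction in \[0, 1\]; `NA` for a zero-length region.
#' @export
coverage_fraction <- function(segs, region, genome) {
  denom <- defined_length(genome, region$chrom, region$start, region$end)
  if (denom == 0) return(NA_real_)
  m <- segs$segments[[region$chrom]]
  if (is.null(m)) return(0)
  sum(m[, 2L] - m[, 1L]) / denom
}

# number of sorted points in [a, b); positions and windows integer-valued
count_in_windows <- function(p, win_start, win_end) {
  p <- sort(p)
  findInterval(win_end - 0.5, p) - findInterval(win_start - 0.5, p)
}

#' Correlation between per-segment point counts and segment marks
#'
#' Builds one counting window per marked segment (the segment itself, or a
#' window anchored at the segment start -- the TSS for gene tracks --
#' extended by `flank` bp on both sides), counts the points in each window,
#' and returns Kendall's tie-corrected tau-b between counts and marks.
#' Count data carry many ties, hence tau-b.
#'
#' @param points a `PointTrack`.
#' @param marked a `MarkedSegmentTrack` with numeric marks.
#' @param flank window extension in bp (default 0).
#' @param anchor `"segment"` (window = segment +/- flank) or `"start"`
#'   (window = \[start - flank, start + flank + 1)).
#' @return tau-b in \[-1, 1\]; `NA` with fewer than 2 segments or constant
#'   input.
#' @export
count_vs_mark_tau <- function(points, marked, flank = 0,
                              anchor = c("segment", "start")) {
  v <- count_mark_vectors(points, marked, flank, match.arg(anchor))
  kendall_tau_b(v$x, v$y)
}

# per-segment point counts (x) and marks (y)
count_mark_vectors <- function(points, marked, flank = 0,
                               anchor = "segment") {
  counts <- numeric(); marks <- numeric()
  for (ch in track_chroms(marked)) {
    m <- marked$segments[[ch]]
    if (!nrow(m)) next
    if (anchor == "segment") {
      ws <- m[, 1L] - flank; we <- m[, 2L] + flank
    } else {
      ws <- m[, 1L] - flank; we <- m[, 1L] + flank + 1
    }
    p <- points$positions[[ch]]
    if (is.null(p)) p <- numeric()
    counts <- c(counts, count_in_windows(p, ws, we))
    mk <- marked$marks[[ch]]
    if (!is.numeric(mk))
      stop("count_vs_mark_tau requires numeric marks")
    marks <- c(marks, mk)
  }
  list(x = counts, y = marks)
}

# tau-b via stats::cor; NA on degenerate input rather than a warning
kendall_tau_b <- function(x, y) {
  if (length(x) < 2L || length(y) != length(x)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

#' Mean function value at point positions
#'
#' Arithmetic mean of a function track evaluated at each point.  Points on
#' undefined (masked) positions are excluded; their count is reported via
#' a message when positive.
#'
#' @param f a `FunctionTrack`.
#' @param points a `PointTrack`.
#' @return mean value; `NA` when no point falls on a defined position.
#' @export
mean_function_at_points <- function(f, points) {
  vals <- numeric(); n_undefined <- 0L
  for (ch in track_chroms(points)) {
    p <- points$positions[[ch]]
    v <- f$values[[ch]]
    if (!length(p)) next
    if (is.null(v)) { n_undefined <- n_undefined + length(p); next }
    at <- rep(NA_real_, length(p))
    ok <- p < length(v)
    at[ok] <- v[p[ok] + 1]
    n_undefined <- n_undefined + sum(is.na(at))
    vals <- c(vals, at[!is.na(at)])
  }
  if (n_undefined > 0L)
    message(n_undefined, " point(s) on undefined function positions excluded")
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Border affinity of points within segments
#'
#' Mean, over points lying inside a segment, of the relative distance to
#' the nearest segment border: `min(p - s, e - 1 - p) / (e - s)`.  Values
#' near 0 indicate accumulation at segment borders; uniform placement gives
#' about 0.25.  The relative (length-normalized) form makes segments of
#' different lengths comparable.
#'
#' @inheritParams points_in_segments
#' @return mean relative border distance in \[0, 0.5\]; `NA` with no
#'   inside points.
#' @export
border_affinity <- function(points, segs) {
  d <- numeric()
  for (ch in track_chroms(points)) {
    p <- points$positions[[ch]]
    m <- segs$segments[[ch]]
    if (is.null(m) || !nrow(m) || !length(p)) next
    idx <- findInterval(p, m[, 1L])
    inside <- idx > 0
    inside[inside] <- p[inside] < m[idx[inside], 2L]
    if (!any(inside)) next
    s <- m[idx[inside], 1L]; e <- m[idx[inside], 2L]
    pi_ <- p[inside]
    d <- c(d, pmin(pi_ - s, e - 1 - pi_) / (e - s))
  }
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Mean distance from points to the nearest segment
#'
#' Points inside a segment contribute 0; a point left of a segment start
#' `s` contributes `s - p`, and a point right of the last covered bp
#' `e - 1` contributes `p - (e - 1)`.
#'
#' @inheritParams points_in_segments
#' @return mean distance in bp; `NA` with no points or no segments.
#' @export
mean_nearest_segment_distance <- function(points, segs) {
  d <- numeric()
  for (ch in track_chroms(points)) {
    p <- points$positions[[ch]]
    m <- segs$segments[[ch]]
    if (is.null(m) || !nrow(m) || !length(p)) next
    idx <- findInterval(p, m[, 1L])
    dist_prev <- ifelse(idx > 0,
                        pmax(0, p - (m[pmax(idx, 1L), 2L] - 1)),
                        Inf)
    dist_next <- ifelse(idx < nrow(m),
                        m[pmin(idx + 1L, nrow(m)), 1L] - p,
                        Inf)
    d <- c(d, pmin(dist_prev, dist_next))
  }
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Mean distance from points to the nearest point of another track
#'
#' @param a,b `PointTrack`s; distances run from each `a` point to the
#'   nearest `b` point.
#' @return mean distance in bp; `NA` when either track is empty.
#' @export
mean_nearest_point_distance <- function(a, b) {
  segs <- new_track(list(segments = lapply(b$positions, function(p)
    cbind(start = p, end = p + 1))), "SegmentTrack")
  mean_nearest_segment_distance(a, segs)
}

#' Mark means of segments split by overlap with another track
#'
#' Splits the marked segments of `b` into those intersecting at least one
#' segment of `a` and the rest, and returns the two group means.
#'
#' @param a a `SegmentTrack`.
#' @param b a `MarkedSegmentTrack` with numeric marks.
#' @return list with `mean_overlap`, `mean_rest`, `difference`
#'   (overlap minus rest), `n_overlap`, `n_rest`; means are `NA` for empty
#'   groups, and `difference` is `NA` when either group is empty.
#' @export
marks_overlap_split <- function(a, b) {
  overlap_marks <- numeric(); rest_marks <- numeric()
  for (ch in track_chroms(b)) {
    m <- b$segments[[ch]]
    if (!nrow(m)) next
    mk <- b$marks[[ch]]
    if (!is.numeric(mk)) stop("marks_overlap_split requires numeric marks")
    am <- a$segments[[ch]]
    if (is.null(am) || !nrow(am)) {
      rest_marks <- c(rest_marks, mk)
      next
    }
    hits <- IRanges::overlapsAny(segments_to_iranges(m),
                                 segments_to_iranges(am))
    overlap_marks <- c(overlap_marks, mk[hits])
    rest_marks <- c(rest_marks, mk[!hits])
  }
  mo <- if (length(overlap_marks)) mean(overlap_marks) else NA_real_
  mr <- if (length(rest_marks)) mean(rest_marks) else NA_real_
  list(mean_overlap = mo, mean_rest = mr,
       difference = if (is.na(mo) || is.na(mr)) NA_real_ else mo - mr,
       n_overlap = length(overlap_marks), n_rest = length(rest_marks))
}

# per-bp values of f jointly defined with g, pooled over shared chromosomes
joint_function_values <- function(f, g) {
  xs <- numeric(); ys <- numeric()
  for (ch in intersect(track_chroms(f), track_chroms(g))) {
    vf <- f$values[[ch]]; vg <- g$values[[ch]]
    n <- min(length(vf), length(vg))
    if (!n) next
    vf <- vf[seq_len(n)]; vg <- vg[seq_len(n)]
    ok <- !is.na(vf) & !is.na(vg)
    xs <- c(xs, vf[ok]); ys <- c(ys, vg[ok])
  }
  list(x = xs, y = ys)
}

#' Correlation between two function tracks
#'
#' Computed over the base pairs where both functions are defined.
#'
#' @param f,g `FunctionTrack`s.
#' @param method `"kendall"` (tau-b, default) or `"pearson"`.
#' @return correlation; `NA` with fewer than 2 jointly defined bp or
#'   constant input.
#' @export
function_correlation <- function(f, g, method = c("kendall", "pearson")) {
  method <- match.arg(method)
  j <- joint_function_values(f, g)
  if (length(j$x) < 2L) return(NA_real_)
  if (stats::sd(j$x) == 0 || stats::sd(j$y) == 0) return(NA_real_)
  stats::cor(j$x, j$y, method = method)
}

#' Mean difference between two function tracks
#'
#' @inheritParams function_correlation
#' @return mean of `f - g` over jointly defined bp; `NA` when none.
#' @export
mean_function_difference <- function(f, g) {
  j <- joint_function_values(f, g)
  if (!length(j$x)) return(NA_real_)
  mean(j$x - j$y)
}

#' Mean function value inside versus outside segments
#'
#' @param f a `FunctionTrack`.
#' @param segs a `SegmentTrack`.
#' @return list with `mean_inside`, `mean_outside` and `difference`
#'   (inside minus outside); components are `NA` where a group has no
#'   defined bp.
#' @export
function_in_segments <- function(f, segs) {
  ins <- numeric(); outs <- numeric()
  for (ch in track_chroms(f)) {
    v <- f$values[[ch]]
    if (!length(v)) next
    covered <- rep(FALSE, length(v))
    m <- segs$segments[[ch]]
    if (!is.null(m) && nrow(m)) {
      for (i in seq_len(nrow(m))) {
        lo <- max(1L, as.integer(m[i, 1L]) + 1L)
        hi <- min(length(v), as.integer(m[i, 2L]))
        if (lo <= hi) covered[lo:hi] <- TRUE
      }
    }
    def <- !is.na(v)
    ins <- c(ins, v[def & covered]); outs <- c(outs, v[def & !covered])
  }
  mi <- if (length(ins)) mean(ins) else NA_real_
  mo <- if (length(outs)) mean(outs) else NA_real_
  list(mean_inside = mi, mean_outside = mo,
       difference = if (is.na(mi) || is.na(mo)) NA_real_ else mi - mo)
}

#' Correlation of per-window element counts or coverage
#'
#' Splits a region into equal sub-windows and correlates the per-window
#' summaries of two tracks: point counts for `PointTrack`s, covered bp for
#' `SegmentTrack`s.  Used by the same-type correlation analyses.
#'
#' @param a,b two tracks of type UP or US.
#' @param region list with `chrom`, `start`, `end`.
#' @param n_windows number of equal sub-windows (default 10).
#' @return Kendall tau-b of the two per-window summary vectors.
#' @export
windowed_correlation <- function(a, b, region, n_windows = 10L) {
  v <- window_summaries(a, b, region, n_windows)
  kendall_tau_b(v$x, v$y)
}

# per-window summaries backing windowed_correlation
window_summaries <- function(a, b, region, n_windows = 10L) {
  edges <- seq(region$start, region$end, length.out = n_windows + 1L)
  ws <- floor(edges[-length(edges)]); we <- floor(edges[-1L])
  summarize <- function(tr) {
    if (infer_type(tr) %in% c("UP", "MP")) {
      p <- tr$positions[[region$chrom]]
      if (is.null(p)) p <- numeric()
      count_in_windows(p, ws, we)
    } else {
      m <- tr$segments[[region$chrom]]
      if (is.null(m)) m <- as_segment_matrix(NULL)
      vapply(seq_along(ws), function(i) {
        s <- pmax(m[, 1L], ws[i]); e <- pmin(m[, 2L], we[i])
        sum(pmax(0, e - s))
      }, numeric(1L))
    }
  }
  list(x = summarize(a), y = summarize(b))
}
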