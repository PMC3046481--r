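# Preservation rules and randomization processes.  A null model fixes part
# of each track's structure and regenerates the rest by a stochastic
# process, confined to the analysis bin (local analyses) or chromosome
# (global analyses).  The segment hierarchy, from strict to loose:
#   preserve_all        -- the track is never altered
#   permute_lengths_gaps -- keep segment and gap length multisets, permute
#                          their order (gaps include both bin flanks)
#   uniform_position    -- keep segment lengths, place disjointly uniformly
#   coverage_bp         -- keep only the covered-bp count (exact,
#                          hypergeometric marginals)
#   coverage_bernoulli  -- iid per-bp coverage at the observed rate (the
#                          variant matching the analytic binomial null)
# Point rules: preserve_all, uniform (without replacement over defined
# bp), intensity (sampling weights proportional to a per-bp intensity).
# Mark rule: permute_marks.  Functions are always conserved.

#' Preservation / randomization rules
#'
#' Rule identifiers accepted by [null_model_spec()], grouped by the track
#' type they apply to.
#' @format named list of character vectors.
#' @export
PRESERVATION_RULES <- list(
  segments = c("preserve_all", "permute_lengths_gaps", "uniform_position",
               "coverage_bp", "coverage_bernoulli"),
  points = c("preserve_all", "uniform", "intensity"),
  marks = c("fixed", "permuted"))

# size-safe permutation (sample(x) on a length-1 x would draw from 1:x)
resample <- function(x) x[sample.int(length(x))]

#' Permute segment and gap order (preserve lengths and gaps)
#'
#' Returns a new segment arrangement inside the bin whose multiset of
#' segment lengths *and* multiset of gap lengths equal the input's (n
#' segments give n + 1 gaps, counting both flanking gaps to the bin
#' edges); segment order and gap order are permuted independently and
#' uniformly.  This preserves the dependency between neighbouring base
#' pairs within segments and gaps, and is deliberately coarser than
#' uniform placement: a single segment can only start at one of the
#' distinct partial gap sums.
#'
#' @param segs `SegmentTrack` clipped to the bin, one chromosome.
#' @param bin list with `chrom`, `start`, `end`.
#' @return a `SegmentTrack` in the bin with the same length multisets.
#' @export
randomize_segments_permute <- function(segs, bin) {
  ch <- as.character(bin$chrom)
  m <- segs$segments[[ch]]
  if (is.null(m) || nrow(m) == 0L) return(segs)
  n <- nrow(m)
  lens <- m[, 2L] - m[, 1L]
  gaps <- c(m[1L, 1L] - bin$start,
            if (n > 1L) m[-1L, 1L] - m[-n, 2L],
            bin$end - m[n, 2L])
  stopifnot(all(gaps >= 0), sum(gaps) + sum(lens) == bin$end - bin$start)
  new_lens <- resample(unname(lens))
  new_gaps <- resample(unname(gaps))
  starts <- bin$start + cumsum(new_gaps)[seq_along(new_lens)] +
    c(0, cumsum(new_lens))[seq_along(new_lens)]
  new_track(list(segments = setNames(
    list(cbind(start = starts, end = starts + new_lens)), ch)),
    "SegmentTrack")
}

#' Place segments uniformly (preserve lengths only)
#'
#' Keeps the segment-length multiset and places the segments disjointly,
#' uniformly over all disjoint arrangements in the bin: the n + 1
#' nonnegative inter-segment gaps are drawn uniformly among compositions
#' of the free space, and the segment order is randomized.  A single
#' segment of length L in a bin of length B starts uniformly on
#' `{0, ..., B - L}`.
#'
#' @inheritParams randomize_segments_permute
#' @return a `SegmentTrack`; error if the segments cannot fit.
#' @export
randomize_segments_uniform <- function(segs, bin) {
  ch <- as.character(bin$chrom)
  m <- segs$segments[[ch]]
  if (is.null(m) || nrow(m) == 0L) return(segs)
  lens <- m[, 2L] - m[, 1L]
  B <- bin$end - bin$start
  free <- B - sum(lens)
  if (free < 0) stop("total segment length exceeds bin length")
  n <- length(lens)
  # uniform composition of `free` into n + 1 nonnegative parts
  # (stars and bars: n distinct cut slots among free + n)
  cuts <- if (free + n > 0) sort(sample.int(free + n, n)) else integer()
  gaps <- diff(c(0, cuts, free + n + 1)) - 1
  stopifnot(length(gaps) == n + 1, all(gaps >= 0), sum(gaps) == free)
  new_lens <- resample(unname(lens))
  starts <- bin$start + cumsum(gaps)[seq_len(n)] +
    c(0, cumsum(new_lens))[seq_len(n)]
  new_track(list(segments = setNames(
    list(cbind(start = starts, end = starts + new_lens)), ch)),
    "SegmentTrack")
}

#' Resample covered base pairs (preserve bp count only)
#'
#' Chooses exactly k covered bp (k = the input's covered-bp count)
#' uniformly without replacement among the bin's bp and returns them as
#' maximal runs; each bp is covered with marginal probability k / B.
#' The `bernoulli` variant instead covers each bp independently with
#' probability k / B, matching the analytic binomial null.
#'
#' @inheritParams randomize_segments_permute
#' @param variant `"exact"` (default, exactly k bp) or `"bernoulli"`.
#' @return a `SegmentTrack`.
#' @export
randomize_coverage_bp <- function(segs, bin, variant = c("exact",
                                                         "bernoulli")) {
  variant <- match.arg(variant)
  ch <- as.character(bin$chrom)
  m <- segs$segments[[ch]]
  B <- as.integer(bin$end - bin$start)
  k <- if (is.null(m)) 0L else as.integer(sum(m[, 2L] - m[, 1L]))
  covered_idx <- if (variant == "exact") {
    if (k > 0L) sort(sample.int(B, k)) else integer()
  } else {
    which(stats::runif(B) < k / B)
  }
  new_track(list(segments = setNames(list(runs_to_segments(
    covered_idx, offset = bin$start)), ch)), "SegmentTrack")
}

# 1-based in-bin indices of covered bp -> 0-based [start, end) matrix
runs_to_segments <- function(idx, offset = 0) {
  if (!length(idx)) return(as_segment_matrix(NULL))
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  starts <- idx[brk[-length(brk)] + 1L] - 1L + offset
  ends <- idx[brk[-1L]] + offset
  cbind(start = as.numeric(starts), end = as.numeric(ends))
}

#' Randomize points uniformly over the defined bin
#'
#' Samples n distinct positions (n = the input point count) uniformly
#' without replacement from the bin's defined (unmasked) base pairs.
#'
#' @param points `PointTrack` clipped to the bin.
#' @param bin list with `chrom`, `start`, `end`.
#' @param genome a [genome_context()] (for the mask).
#' @return a `PointTrack`.
#' @export
randomize_points_uniform <- function(points, bin, genome) {
  ch <- as.character(bin$chrom)
  p <- points$positions[[ch]]
  n <- length(p)
  if (n == 0L) return(points)
  cand <- defined_positions(genome, ch, bin$start, bin$end)
  if (n > length(cand))
    stop("more points than defined bp in the bin")
  point_track(setNames(list(sort(cand[sample.int(length(cand), n)])), ch))
}

#' Randomize points by a per-bp intensity
#'
#' Samples n distinct positions without replacement with probability
#' proportional to the intensity lambda(b), i.e. a non-homogeneous
#' Poisson process conditioned on the observed point count.  A constant
#' intensity reduces to uniform randomization.  Sampling without
#' replacement uses sequential weighted draws; for n much smaller than
#' the bin this is numerically indistinguishable from the conditioned
#' process.
#'
#' @inheritParams randomize_points_uniform
#' @param intensity an [IntensityTrack][constant_intensity()] (a
#'   `FunctionTrack` with nonnegative values) defined on the bin.
#' @return a `PointTrack`.
#' @export
randomize_points_intensity <- function(points, bin, intensity, genome) {
  ch <- as.character(bin$chrom)
  p <- points$positions[[ch]]
  n <- length(p)
  if (n == 0L) return(points)
  cand <- defined_positions(genome, ch, bin$start, bin$end)
  v <- intensity$values[[ch]]
  lam <- rep(NA_real_, length(cand))
  ok <- cand < length(v)
  lam[ok] <- v[cand[ok] + 1]
  if (any(lam < 0, na.rm = TRUE))
    stop("intensity must be nonnegative")
  usable <- !is.na(lam) & lam > 0
  if (sum(usable) < n)
    stop("intensity has fewer than n positive defined bp in the bin")
  pos <- cand[usable]; w <- lam[usable]
  point_track(setNames(list(sort(pos[sample.int(length(pos), n,
                                                prob = w)])), ch))
}

#' Permute the marks of a marked track
#'
#' Positions (or segments) stay fixed; the marks are uniformly permuted
#' within each chromosome.  The permutation null for the correlation
#' analyses.
#'
#' @param track a `MarkedPointTrack` or `MarkedSegmentTrack`.
#' @return track of the same type with permuted marks.
#' @export
permute_marks <- function(track) {
  type <- infer_type(track)
  if (!type %in% c("MP", "MS"))
    stop("permute_marks applies to marked tracks only")
  track$marks <- lapply(track$marks, function(m)
    if (length(m) > 1L) sample(m) else m)
  track
}

#' Specify a null model for a track pair
#'
#' A null model names, per track, the preservation rule (what stays as in
#' the data) and implicitly the randomization regenerating the rest.
#' `preserve_all` tracks pass through untouched; randomizing both tracks
#' composes independent randomizers.
#'
#' @param t1,t2 rule for each track: one of
#'   `r paste(unique(unlist(PRESERVATION_RULES)), collapse = ", ")`.
#' @param intensity optional intensity track, required when either rule is
#'   `"intensity"`.
#' @return a `NullModelSpec`.
#' @examples
#' null_model_spec("permute_lengths_gaps", "preserve_all")
#' @export
null_model_spec <- function(t1 = "preserve_all", t2 = "preserve_all",
                            intensity = NULL) {
  all_rules <- c(unique(unlist(PRESERVATION_RULES)), "permute_marks")
  for (r in c(t1, t2))
    if (!r %in% all_rules) stop("unknown preservation rule: ", r)
  if (("intensity" %in% c(t1, t2)) && is.null(intensity))
    stop("the intensity rule requires an intensity track")
  structure(list(t1 = t1, t2 = t2, intensity = intensity),
            class = "NullModelSpec")
}

# apply a single-track rule in a bin
apply_rule <- function(track, rule, bin, genome, intensity) {
  type <- infer_type(track)
  switch(rule,
    preserve_all = track,
    permute_lengths_gaps = {
      stopifnot(type %in% c("US", "MS"))
      randomize_segments_permute(require_unmarked(track), bin)
    },
    uniform_position = {
      stopifnot(type %in% c("US", "MS"))
      randomize_segments_uniform(require_unmarked(track), bin)
    },
    coverage_bp = {
      stopifnot(type %in% c("US", "MS"))
      randomize_coverage_bp(require_unmarked(track), bin, "exact")
    },
    coverage_bernoulli = {
      stopifnot(type %in% c("US", "MS"))
      randomize_coverage_bp(require_unmarked(track), bin, "bernoulli")
    },
    uniform = {
      stopifnot(type %in% c("UP", "MP"))
      randomize_points_uniform(require_unmarked(track), bin, genome)
    },
    intensity = {
      stopifnot(type %in% c("UP", "MP"))
      randomize_points_intensity(require_unmarked(track), bin, intensity,
                                 genome)
    },
    permute_marks = permute_marks(track),
    stop("rule ", rule, " is incompatible with track type ", type))
}

# marked tracks lose their marks when their positions are randomized
require_unmarked <- function(track) {
  type <- infer_type(track)
  if (type == "MS") coerce_track(track, "US")
  else if (type == "MP") coerce_track(track, "UP")
  else track
}

#' Build a joint randomizer from a null-model specification
#'
#' Returns a closure mapping `(t1, t2, bin)` to one joint replicate of the
#' track pair under the null model.  Function tracks are always conserved.
#' Reproducibility contract: with the same RNG state (e.g. after
#' `set.seed`) the replicate is bit-identical.
#'
#' @param spec a [null_model_spec()].
#' @param genome a [genome_context()].
#' @return `function(t1, t2, bin)` returning `list(t1 = , t2 = )`.
#' @export
build_randomizer <- function(spec, genome) {
  force(spec); force(genome)
  function(t1, t2, bin) {
    list(t1 = apply_rule(t1, spec$t1, bin, genome, spec$intensity),
         t2 = apply_rule(t2, spec$t2, bin, genome, spec$intensity))
  }
}
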