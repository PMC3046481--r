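#' The five genomic types
#'
#' Every one-dimensional genome annotation reduces to one of five abstract
#' types: unmarked points (`UP`), marked points (`MP`), unmarked segments
#' (`US`), marked segments (`MS`) and per-bp functions (`F`).  SNPs reduce
#' to points, genes to segments, expression values ride along as marks, and
#' quantities like DNA melting temperature are functions assigning a value
#' to each base pair.
#'
#' @format character vector of the five type symbols.
#' @export
TRACK_TYPES <- c("UP", "MP", "US", "MS", "F")

new_track <- function(data, class) {
  structure(data, class = c(class, "Track"))
}

check_chrom_list <- function(x, what) {
  if (!is.list(x) || (length(x) && is.null(names(x))))
    stop(what, " must be a named list (one element per chromosome)")
  x
}

#' Construct a point track (UP)
#'
#' Positions are 0-based bp offsets, one sorted vector per chromosome.
#' Duplicate positions are rejected: a point track is a set of distinct
#' sites, and the point randomizers sample positions without replacement.
#'
#' @param positions named list of numeric vectors of 0-based positions.
#' @return a `PointTrack`.
#' @examples
#' point_track(list(chrT = c(3, 10, 42)))
#' @export
point_track <- function(positions) {
  positions <- check_chrom_list(positions, "positions")
  positions <- lapply(positions, function(p) {
    p <- as.numeric(p)
    if (anyNA(p) || any(!is.finite(p))) stop("positions must be finite")
    p <- sort(p)
    if (anyDuplicated(p)) stop("duplicate point positions are not allowed")
    p
  })
  new_track(list(positions = positions), "PointTrack")
}

#' Construct a marked point track (MP)
#'
#' @inheritParams point_track
#' @param marks named list of mark vectors (numeric or character), parallel
#'   to `positions`.  Marks follow their point when positions are sorted.
#' @return a `MarkedPointTrack`.
#' @export
marked_point_track <- function(positions, marks) {
  positions <- check_chrom_list(positions, "positions")
  marks <- check_chrom_list(marks, "marks")
  if (!setequal(names(positions), names(marks)))
    stop("positions and marks must cover the same chromosomes")
  ord <- lapply(positions, function(p) order(as.numeric(p)))
  pt <- point_track(positions)
  marks <- lapply(setNames(names(positions), names(positions)), function(ch) {
    m <- marks[[ch]]
    if (length(m) != length(positions[[ch]]))
      stop("marks length must equal point count on ", ch)
    if (is.numeric(m) && any(!is.finite(m)))
      stop("numeric marks must be finite")
    m[ord[[ch]]]
  })
  new_track(list(positions = pt$positions, marks = marks), "MarkedPointTrack")
}

#' Construct a segment track (US)
#'
#' Segments are half-open intervals `[start, end)` in 0-based bp, one
#' two-column matrix per chromosome.  Unsorted input is sorted; touching or
#' overlapping segments are merged with a warning (the randomizers and
#' overlap statistics assume disjoint segments).
#'
#' @param segments named list of two-column `start`/`end` matrices.
#' @return a `SegmentTrack`.
#' @examples
#' segment_track(list(chrT = cbind(c(0, 20), c(10, 35))))
#' @export
segment_track <- function(segments) {
  segments <- check_chrom_list(segments, "segments")
  merged_total <- 0L
  segments <- lapply(segments, function(m) {
    m <- as_segment_matrix(m)
    if (any(!is.finite(m))) stop("segment coordinates must be finite")
    if (any(m[, 1L] >= m[, 2L]))
      stop("every segment must satisfy start < end")
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    out <- merge_touching(m)
    merged_total <<- merged_total + (nrow(m) - nrow(out))
    out
  })
  if (merged_total > 0L)
    warning("merged ", merged_total,
            " overlapping/touching segment(s) during normalization")
  new_track(list(segments = segments), "SegmentTrack")
}

# merge sorted intervals that overlap or touch; returns disjoint matrix
merge_touching <- function(m) {
  if (nrow(m) < 2L) return(m)
  s <- m[, 1L]; e <- m[, 2L]
  keep_start <- c(TRUE, s[-1L] > cummax(e[-length(e)]))
  grp <- cumsum(keep_start)
  out <- cbind(start = as.numeric(tapply(s, grp, min)),
               end = as.numeric(tapply(e, grp, max)))
  colnames(out) <- c("start", "end")
  out
}

#' Construct a marked segment track (MS)
#'
#' Like [segment_track()] but with one mark per segment (e.g. an expression
#' value).  Because marks are per-segment, overlapping segments cannot be
#' merged and are rejected instead.
#'
#' @inheritParams segment_track
#' @param marks named list of mark vectors, one value per segment.
#' @return a `MarkedSegmentTrack`.
#' @export
marked_segment_track <- function(segments, marks) {
  segments <- check_chrom_list(segments, "segments")
  marks <- check_chrom_list(marks, "marks")
  if (!setequal(names(segments), names(marks)))
    stop("segments and marks must cover the same chromosomes")
  out_segments <- list(); out_marks <- list()
  for (ch in names(segments)) {
    m <- as_segment_matrix(segments[[ch]])
    mk <- marks[[ch]]
    if (length(mk) != nrow(m))
      stop("marks length must equal segment count on ", ch)
    if (is.numeric(mk) && any(!is.finite(mk)))
      stop("numeric marks must be finite")
    if (any(m[, 1L] >= m[, 2L]))
      stop("every segment must satisfy start < end")
    o <- order(m[, 1L], m[, 2L])
    m <- m[o, , drop = FALSE]; mk <- mk[o]
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
      stop("overlapping segments are not allowed in a marked segment track")
    out_segments[[ch]] <- m; out_marks[[ch]] <- mk
  }
  new_track(list(segments = out_segments, marks = out_marks),
            "MarkedSegmentTrack")
}

#' Construct a function track (F)
#'
#' A function track assigns one value to each base pair of its defined
#' region; `NA` flags positions where the function is undefined.  The value
#' vector for a chromosome runs over `[0, length(values))` in bp.
#'
#' @param values named list of numeric vectors, one value per bp from
#'   position 0; `NA` where undefined.
#' @return a `FunctionTrack`.
#' @export
function_track <- function(values) {
  values <- check_chrom_list(values, "values")
  values <- lapply(values, function(v) {
    v <- as.numeric(v)
    if (any(is.infinite(v)))
      stop("function values must be finite where defined (use NA)")
    v
  })
  new_track(list(values = values), "FunctionTrack")
}

#' Chromosomes a track carries data for
#' @param track a track object.
#' @return character vector of chromosome names.
#' @export
track_chroms <- function(track) {
  names(track[[1L]])
}

#' Number of elements per chromosome
#' @param track a track object.
#' @return named integer vector: points, segments, or defined bp per
#'   chromosome.
#' @export
track_counts <- function(track) {
  switch(infer_type(track),
         UP = , MP = vapply(track$positions, length, 1L),
         US = , MS = vapply(track$segments, nrow, 1L),
         "F" = vapply(track$values, function(v) sum(!is.na(v)), 1L))
}

#' Detect the genomic type of a track
#'
#' Returns the minimal-information type symbol of the concrete
#' representation, one of `"UP"`, `"MP"`, `"US"`, `"MS"`, `"F"`.
#'
#' @param track a track object.
#' @return one of [TRACK_TYPES].
#' @export
infer_type <- function(track) {
  if (inherits(track, "MarkedPointTrack")) return("MP")
  if (inherits(track, "PointTrack")) return("UP")
  if (inherits(track, "MarkedSegmentTrack")) return("MS")
  if (inherits(track, "SegmentTrack")) return("US")
  if (inherits(track, "FunctionTrack")) return("F")
  stop("not a recognized track representation")
}

#' Information-reducing type coercion
#'
#' Converts a track to a simpler genomic type by discarding information:
#' marks can be dropped (MS to US, MP to UP), and segments can be reduced
#' to points (MS/US to MP/UP) either by their middle points
#' (`floor((start + end) / 2)`, deterministic) or by their boundaries.
#' Information-increasing conversions (e.g. UP to US) are rejected.
#' Coercion to the current type returns the track unchanged.
#'
#' @param track a track object.
#' @param target target type symbol, one of [TRACK_TYPES].
#' @param reduction how segments become points: `"midpoint"` (default),
#'   `"start"`, `"end"`, or `"boundaries"` (both endpoints; the right
#'   endpoint is the last bp of the segment, `end - 1`).
#' @return a track of type `target`.
#' @examples
#' us <- segment_track(list(chrT = cbind(c(0, 8), c(5, 9))))
#' coerce_track(us, "UP")$positions$chrT  # 2, 8
#' @export
coerce_track <- function(track, target,
                         reduction = c("midpoint", "start", "end",
                                       "boundaries")) {
  target <- match.arg(target, TRACK_TYPES)
  reduction <- match.arg(reduction)
  from <- infer_type(track)
  if (from == target) return(track)
  seg_to_points <- function(m) {
    switch(reduction,
           midpoint = floor((m[, 1L] + m[, 2L]) / 2),
           start = m[, 1L],
           end = m[, 2L] - 1,
           boundaries = sort(unique(c(m[, 1L], m[, 2L] - 1))))
  }
  ok <- paste(from, target, sep = "->")
  switch(ok,
    "MP->UP" = point_track(track$positions),
    "MS->US" = new_track(list(segments = track$segments), "SegmentTrack"),
    "MS->UP" = point_track(lapply(track$segments, seg_to_points)),
    "MS->MP" = {
      if (reduction == "boundaries")
        stop("boundary reduction cannot carry per-segment marks")
      marked_point_track(lapply(track$segments, seg_to_points), track$marks)
    },
    "US->UP" = point_track(lapply(track$segments, seg_to_points)),
    stop("coercion ", from, " -> ", target,
         " would require adding information; only reductions are allowed"))
}

#' Validate a track against a genome context
#'
#' Checks every type invariant (sortedness, bounds, mask membership, mark
#' lengths, finiteness) and returns the violations as a character vector
#' rather than raising: an empty vector means the track is valid.
#'
#' @param track a track object.
#' @param genome a [genome_context()].
#' @return character vector of violation messages (empty if valid).
#' @export
validate_track <- function(track, genome) {
  v <- character()
  type <- tryCatch(infer_type(track), error = function(e) NA_character_)
  if (is.na(type)) return("unrecognized track representation")
  for (ch in track_chroms(track)) {
    if (!ch %in% chrom_names(genome)) {
      v <- c(v, paste0("unknown chromosome: ", ch))
      next
    }
    L <- chrom_length(genome, ch)
    if (type %in% c("UP", "MP")) {
      p <- track$positions[[ch]]
      if (is.unsorted(p, strictly = TRUE))
        v <- c(v, paste0(ch, ": positions not strictly increasing"))
      if (length(p) && (min(p) < 0 || max(p) >= L))
        v <- c(v, paste0(ch, ": position outside [0, ", L, ")"))
      if (length(p) && !all(position_defined(genome, ch, p)))
        v <- c(v, paste0(ch, ": position outside defined regions"))
      if (type == "MP" && length(track$marks[[ch]]) != length(p))
        v <- c(v, paste0(ch, ": marks length != point count"))
    } else if (type %in% c("US", "MS")) {
      m <- track$segments[[ch]]
      if (any(m[, 1L] >= m[, 2L]))
        v <- c(v, paste0(ch, ": segment with start >= end"))
      if (nrow(m) > 1L && any(diff(m[, 1L]) < 0))
        v <- c(v, paste0(ch, ": segments not sorted by start"))
      if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
        v <- c(v, paste0(ch, ": overlapping segments"))
      if (nrow(m) && (min(m[, 1L]) < 0 || max(m[, 2L]) > L))
        v <- c(v, paste0(ch, ": segment outside [0, ", L, ")"))
      if (nrow(m) && !all(segment_defined(genome, ch, m)))
        v <- c(v, paste0(ch, ": segment outside defined regions"))
      if (type == "MS" && length(track$marks[[ch]]) != nrow(m))
        v <- c(v, paste0(ch, ": marks length != segment count"))
    } else if (type == "F") {
      val <- track$values[[ch]]
      if (length(val) > L)
        v <- c(v, paste0(ch, ": more values than chromosome length"))
      if (any(is.infinite(val)))
        v <- c(v, paste0(ch, ": non-finite function values"))
    }
  }
  v
}

# TRUE for each position lying inside a defined region
position_defined <- function(genome, chrom, pos) {
  m <- defined_regions(genome, chrom)
  if (!nrow(m)) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, m[, 1L])
  ok <- idx > 0
  ok[ok] <- pos[ok] < m[idx[ok], 2L]
  ok
}

# TRUE for each segment fully inside a single defined region
segment_defined <- function(genome, chrom, seg) {
  m <- defined_regions(genome, chrom)
  if (!nrow(m)) return(rep(FALSE, nrow(seg)))
  idx <- findInterval(seg[, 1L], m[, 1L])
  ok <- idx > 0
  ok[ok] <- seg[ok, 2L] <= m[idx[ok], 2L]
  ok
}

#' @export
print.Track <- function(x, ...) {
  type <- infer_type(x)
  cnt <- track_counts(x)
  cat(type, "track on", length(cnt), "chromosome(s);",
      switch(type, UP = , MP = "points:", US = , MS = "segments:",
             "F" = "defined bp:"),
      sum(cnt), "\n")
  invisible(x)
}
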