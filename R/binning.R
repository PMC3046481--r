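#' Parse a region specification string
#'
#' Accepted forms: `"*"` (whole genome), `"chrN"` (one whole chromosome),
#' `"chrN:A-B"` and `"chrN:A-"` (open end = chromosome end).  `A` and `B`
#' are 1-based inclusive user coordinates; they accept comma grouping and
#' `k`/`m` suffixes.  A suffixed start such as `"3m"` means "after 3
#' megabases", so `"chr17:3m-"` starts at 0-based position 3,000,000.
#'
#' @param spec region string.
#' @param genome a [genome_context()].
#' @return a `RegionSpec`: list with `chrom` (NA for whole genome),
#'   `start`, `end` (0-based half-open), or class `"whole_genome"`.
#' @examples
#' g <- genome_context(c(chr17 = 9e7))
#' parse_region("chr17:3m-", g)
#' @export
parse_region <- function(spec, genome) {
  spec <- gsub("[[:space:]]", "", spec)
  if (spec == "*" || spec == "")
    return(structure(list(chrom = NA_character_, start = NA_real_,
                          end = NA_real_),
                     class = c("whole_genome", "RegionSpec")))
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  chrom <- parts[1L]
  L <- chrom_length(genome, chrom)  # errors on unknown chromosome
  if (length(parts) == 1L)
    return(structure(list(chrom = chrom, start = 0, end = L),
                     class = "RegionSpec"))
  rng <- parts[2L]
  m <- regmatches(rng, regexec("^([0-9,.]+[km]?)?-([0-9,.]+[km]?)?$", rng))[[1L]]
  if (!length(m)) stop("cannot parse region range: ", rng)
  a <- m[2L]; b <- m[3L]
  start <- if (!nzchar(a)) 0 else parse_coord(a, role = "start")
  end <- if (!nzchar(b)) L else parse_coord(b, role = "end")
  if (start >= end)
    stop("empty region: start ", start, " >= end ", end, " (0-based)")
  if (start < 0 || end > L)
    stop("region outside chromosome [0, ", L, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "RegionSpec")
}

# one user coordinate -> 0-based.  Suffixed values ("3m") count whole bp
# from the chromosome start; plain values are 1-based positions.
parse_coord <- function(s, role = c("start", "end")) {
  role <- match.arg(role)
  s <- gsub(",", "", s)
  m <- regmatches(s, regexec("^([0-9.]+)([km]?)$", s))[[1L]]
  if (!length(m)) stop("cannot parse coordinate: ", s)
  v <- as.numeric(m[2L])
  suffixed <- nzchar(m[3L])
  v <- v * switch(m[3L], k = 1e3, m = 1e6, 1)
  if (v != round(v)) stop("coordinate is not a whole bp: ", s)
  if (role == "start") {
    if (suffixed) v else v - 1
  } else {
    v
  }
}

#' Parse a bin-size specification string
#'
#' An integer with an optional `k` (kilobases) or `m` (megabases) suffix and
#' optional internal space: `"5 m"` is 5,000,000 bp.
#'
#' @param spec size string.
#' @return size in bp.
#' @examples
#' parse_size("5 m")
#' parse_size("1k")
#' @export
parse_size <- function(spec) {
  s <- gsub("[[:space:],]", "", spec)
  m <- regmatches(s, regexec("^([0-9.]+)([km]?)$", s))[[1L]]
  if (!length(m)) stop("cannot parse size: ", spec)
  v <- as.numeric(m[2L]) * switch(m[3L], k = 1e3, m = 1e6, 1)
  if (!is.finite(v) || v <= 0 || v != round(v))
    stop("bin size must be a positive whole number of bp: ", spec)
  v
}

#' Partition a region into bins
#'
#' Bins tile the region in consecutive `bin_size` windows from the region
#' start; the last bin of each chromosome is truncated at the region end so
#' the region is covered exactly.  The bin length defines the scale of a
#' local analysis.  Bins never span chromosome boundaries; whole-genome
#' mode bins each chromosome independently.
#'
#' @param region a `RegionSpec` from [parse_region()] (or a whole-genome
#'   spec).
#' @param bin_size bin size in bp (see [parse_size()]).
#' @param genome a [genome_context()].
#' @return a `BinPartition`: data.frame with columns `bin_id`, `chrom`,
#'   `start`, `end` and attribute `bin_size`.
#' @export
make_bins <- function(region, bin_size, genome) {
  if (bin_size <= 0) stop("bin_size must be positive")
  one_chrom <- function(chrom, start, end) {
    if (start >= end) return(NULL)
    starts <- seq(start, end - 1, by = bin_size)
    ends <- pmin(starts + bin_size, end)
    data.frame(chrom = chrom, start = starts, end = ends,
               stringsAsFactors = FALSE)
  }
  if (inherits(region, "whole_genome")) {
    parts <- lapply(chrom_names(genome), function(ch)
      one_chrom(ch, 0, chrom_length(genome, ch)))
    df <- do.call(rbind, parts)
  } else {
    df <- one_chrom(region$chrom, region$start, region$end)
  }
  if (is.null(df) || !nrow(df)) stop("empty region: no bins")
  df <- data.frame(bin_id = sprintf("%s:%d-%d", df$chrom,
                                    as.integer(df$start) + 1L,
                                    as.integer(df$end)),
                   df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, bin_size = bin_size,
            class = c("BinPartition", "data.frame"))
}

#' Restrict a track to one bin
#'
#' Points are filtered to `[start, end)`; segments are intersected with the
#' bin (clipped; marks retained for surviving segments); function values
#' outside the bin are set to undefined.  The returned track carries only
#' the bin's chromosome.
#'
#' @param track a track object.
#' @param bin a list or one-row data.frame with `chrom`, `start`, `end`.
#' @return a track of the same type, restricted to the bin.
#' @export
clip_to_bin <- function(track, bin) {
  ch <- as.character(bin$chrom)
  start <- as.numeric(bin$start); end <- as.numeric(bin$end)
  type <- infer_type(track)
  if (type %in% c("UP", "MP")) {
    p <- track$positions[[ch]]
    if (is.null(p)) p <- numeric()
    keep <- p >= start & p < end
    if (type == "UP") return(point_track(setNames(list(p[keep]), ch)))
    return(marked_point_track(setNames(list(p[keep]), ch),
                              setNames(list(track$marks[[ch]][keep]), ch)))
  }
  if (type %in% c("US", "MS")) {
    m <- track$segments[[ch]]
    if (is.null(m)) m <- as_segment_matrix(NULL)
    s <- unname(pmax(m[, 1L], start)); e <- unname(pmin(m[, 2L], end))
    keep <- s < e
    clipped <- cbind(start = s[keep], end = e[keep])
    if (type == "US")
      return(new_track(list(segments = setNames(list(clipped), ch)),
                       "SegmentTrack"))
    return(new_track(list(segments = setNames(list(clipped), ch),
                          marks = setNames(list(track$marks[[ch]][keep]),
                                           ch)),
                     "MarkedSegmentTrack"))
  }
  # F: keep per-bp values only inside the bin
  v <- track$values[[ch]]
  if (is.null(v)) v <- numeric()
  out <- rep(NA_real_, length(v))
  lo <- max(1L, as.integer(start) + 1L)
  hi <- min(length(v), as.integer(end))
  if (lo <= hi) out[lo:hi] <- v[lo:hi]
  function_track(setNames(list(out), ch))
}

#' Export a bin partition as BED text
#'
#' @param bins a `BinPartition`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bins_bed <- function(bins, path) {
  utils::write.table(data.frame(bins$chrom, as.integer(bins$start),
                                as.integer(bins$end), bins$bin_id),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
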