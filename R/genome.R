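#' Genome coordinate context
#'
#' A `GenomeContext` owns the coordinate convention shared by all tracks: an
#' ordered set of chromosomes with their lengths, plus an optional mask of
#' *defined regions* per chromosome.  A track is defined over the whole
#' genome or only in parts of it; positions outside the defined regions are
#' masked away and take part neither in statistics nor in randomization.
#'
#' All internal coordinates are 0-based, half-open `[start, end)`.
#' User-facing region strings (see [parse_region()]) are 1-based inclusive
#' and converted at the boundary.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp;
#'   names are the chromosome names, order is the genome order.
#' @param defined_regions optional named list; one two-column matrix
#'   (`start`, `end`, 0-based half-open) per chromosome giving the defined
#'   regions.  Chromosomes absent from the list are fully defined.
#' @return an object of class `GenomeContext`.
#' @examples
#' g <- genome_context(c(chrT = 1000))
#' chrom_length(g, "chrT")
#' @export
genome_context <- function(chromosomes, defined_regions = NULL) {
  if (length(chromosomes) == 0L)
    stop("a genome needs at least one chromosome")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chromosomes)))
    stop("duplicate chromosome names")
  chromosomes <- setNames(as.numeric(chromosomes), names(chromosomes))
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0))
    stop("every chromosome length must be a positive finite number")
  if (!is.null(defined_regions)) {
    if (is.null(names(defined_regions)))
      stop("defined_regions must be a named list")
    bad <- setdiff(names(defined_regions), names(chromosomes))
    if (length(bad))
      stop("defined_regions for unknown chromosome(s): ",
           paste(bad, collapse = ", "))
    defined_regions <- lapply(setNames(names(defined_regions),
                                       names(defined_regions)), function(ch) {
      m <- as_segment_matrix(defined_regions[[ch]])
      if (nrow(m)) {
        if (any(m[, 1L] < 0) || any(m[, 2L] > chromosomes[[ch]]))
          stop("defined region outside [0, length) on ", ch)
        if (is.unsorted(m[, 1L], strictly = TRUE) && nrow(m) > 1L)
          m <- m[order(m[, 1L]), , drop = FALSE]
        if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
          stop("defined regions overlap on ", ch)
        if (any(m[, 1L] >= m[, 2L]))
          stop("empty defined region on ", ch)
      }
      m
    })
  }
  structure(list(chromosomes = chromosomes,
                 defined_regions = defined_regions),
            class = "GenomeContext")
}

# coerce assorted two-column inputs (matrix, data.frame) to a start/end matrix
as_segment_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  if (is.vector(x) && length(x) == 2L) x <- matrix(x, ncol = 2L)
  x <- matrix(as.numeric(x), ncol = 2L)
  colnames(x) <- c("start", "end")
  x
}

#' @rdname genome_context
#' @param genome a `GenomeContext`.
#' @export
chrom_names <- function(genome) names(genome$chromosomes)

#' @rdname genome_context
#' @param chrom chromosome name.
#' @export
chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$chromosomes))
    stop("unknown chromosome: ", chrom)
  unname(genome$chromosomes[[chrom]])
}

#' Defined regions of a chromosome window
#'
#' Returns the defined (unmasked) regions of `chrom` intersected with the
#' window `[start, end)`, as a two-column matrix.  With no mask the whole
#' window is returned.
#'
#' @inheritParams chrom_length
#' @param start,end 0-based half-open window; defaults to the whole
#'   chromosome.
#' @return two-column `start`/`end` matrix of disjoint sorted intervals.
#' @export
defined_regions <- function(genome, chrom, start = 0,
                            end = chrom_length(genome, chrom)) {
  L <- chrom_length(genome, chrom)
  start <- max(0, start); end <- min(L, end)
  if (is.null(genome$defined_regions) ||
      is.null(genome$defined_regions[[chrom]])) {
    m <- matrix(c(start, end), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    return(m[m[, 1L] < m[, 2L], , drop = FALSE])
  }
  m <- genome$defined_regions[[chrom]]
  s <- pmax(m[, 1L], start); e <- pmin(m[, 2L], end)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

#' @rdname defined_regions
#' @return `defined_length()`: total number of defined bp in the window.
#' @export
defined_length <- function(genome, chrom, start = 0,
                           end = chrom_length(genome, chrom)) {
  m <- defined_regions(genome, chrom, start, end)
  sum(m[, 2L] - m[, 1L])
}

#' @rdname defined_regions
#' @return `defined_positions()`: integer-valued vector of every defined bp
#'   offset in the window (intended for small windows).
#' @export
defined_positions <- function(genome, chrom, start = 0,
                              end = chrom_length(genome, chrom)) {
  m <- defined_regions(genome, chrom, start, end)
  if (!nrow(m)) return(numeric())
  unlist(lapply(seq_len(nrow(m)),
                function(i) seq(m[i, 1L], m[i, 2L] - 1)), use.names = FALSE)
}

#' @export
print.GenomeContext <- function(x, ...) {
  cat("GenomeContext with", length(x$chromosomes), "chromosome(s)\n")
  n <- utils::head(names(x$chromosomes), 5L)
  for (ch in n) cat("  ", ch, ": ", format(x$chromosomes[[ch]],
                                           big.mark = ","), " bp\n", sep = "")
  if (length(x$chromosomes) > 5L) cat("  ...\n")
  if (!is.null(x$defined_regions))
    cat("  mask present on:", paste(names(x$defined_regions),
                                    collapse = ", "), "\n")
  invisible(x)
}
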