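# File formats: UCSC chrom.sizes, BED (0-based half-open, read natively),
# WIG fixedStep/variableStep (1-based, converted on read), and the TSV
# results table.  BED and WIG parsing is delegated to rtracklayer; the
# writers emit plain deterministic text.

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return a [genome_context()] with full-genome defined regions.
#' @export
read_chrom_sizes <- function(path) {
  df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE,
                                   col.names = c("chrom", "length"),
                                   colClasses = c("character",
                                                  "character")),
                 error = function(e) stop("cannot read chrom.sizes '",
                                          path, "': ",
                                          conditionMessage(e)))
  if (!nrow(df)) stop("chrom.sizes file has no chromosomes: ", path)
  len <- suppressWarnings(as.numeric(df$length))
  if (anyNA(len) || any(len != round(len)))
    stop("non-integer chromosome length in ", path)
  if (anyDuplicated(df$chrom))
    stop("duplicate chromosome name in ", path)
  genome_context(setNames(len, df$chrom))
}

check_chroms <- function(chroms, genome, strict) {
  known <- chroms %in% chrom_names(genome)
  if (all(known)) return(known)
  msg <- paste0("unknown chromosome(s): ",
                paste(unique(chroms[!known]), collapse = ", "))
  if (strict) stop(msg)
  warning(msg, "; entries skipped")
  known
}

#' Read a BED file as a typed track
#'
#' BED is 0-based half-open and is mapped onto the track model without
#' coordinate shifts.  By default the result is a segment track (US); with
#' `as_type = "MS"`/`"MP"` the numeric score column (column 5) becomes the
#' mark; with `as_type = "UP"` every interval must have length 1 and the
#' starts become points.  The BED name column is ignored for statistics.
#'
#' @param path file path.
#' @param genome a [genome_context()].
#' @param as_type optional target type: `"US"` (default), `"MS"`, `"UP"`,
#'   `"MP"`.
#' @param strict fail on unknown chromosomes instead of skipping them
#'   with a warning (default FALSE: real tracks often include scaffolds).
#' @return a track of the requested type.
#' @export
read_bed <- function(path, genome, as_type = NULL, strict = FALSE) {
  gr <- rtracklayer::import(path, format = "bed")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  score <- gr$score
  keep <- check_chroms(chroms, genome, strict)
  chroms <- chroms[keep]; start0 <- start0[keep]; end0 <- end0[keep]
  if (!is.null(score)) score <- score[keep]
  if (!length(chroms)) stop("no usable intervals in ", path)
  for (ch in unique(chroms)) {
    L <- chrom_length(genome, ch)
    sel <- chroms == ch
    if (any(start0[sel] < 0) || any(end0[sel] > L))
      stop("interval outside [0, ", L, ") on ", ch, " in ", path)
  }
  as_type <- as_type %||% "US"
  split_by <- function(x) split(x, factor(chroms, unique(chroms)))
  if (as_type %in% c("UP", "MP")) {
    if (any(end0 - start0 != 1))
      stop("as_type='", as_type, "' requires every interval to have",
           " length 1")
    if (as_type == "UP") return(point_track(split_by(start0)))
    if (is.null(score)) stop("as_type='MP' needs a numeric score column")
    return(marked_point_track(split_by(start0), split_by(score)))
  }
  segs <- lapply(split(seq_along(chroms),
                       factor(chroms, unique(chroms))), function(i)
    cbind(start = start0[i], end = end0[i]))
  if (as_type == "US") return(segment_track(segs))
  if (as_type == "MS") {
    if (is.null(score)) stop("as_type='MS' needs a numeric score column")
    return(marked_segment_track(segs, split_by(score)))
  }
  stop("unsupported as_type: ", as_type)
}

#' Write a track as BED
#'
#' Segments map to BED3 (BED5 with the mark in the score column for
#' marked tracks); points map to length-1 intervals.  Normalized tracks
#' round-trip exactly through [read_bed()].
#'
#' @param track a track of type UP, MP, US or MS.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(track, path) {
  type <- infer_type(track)
  rows <- list()
  for (ch in track_chroms(track)) {
    if (type %in% c("UP", "MP")) {
      p <- track$positions[[ch]]
      if (!length(p)) next
      df <- data.frame(ch, fmt_bp(p), fmt_bp(p + 1))
    } else {
      m <- track$segments[[ch]]
      if (!nrow(m)) next
      df <- data.frame(ch, fmt_bp(m[, 1L]), fmt_bp(m[, 2L]))
    }
    if (type %in% c("MP", "MS"))
      df <- cbind(df, ".", track$marks[[ch]])
    rows[[ch]] <- df
  }
  if (!length(rows)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- lapply(rows, function(df) {
    names(df) <- paste0("V", seq_along(df)); df
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fmt_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a WIG file as a function track
#'
#' Supports `fixedStep` and `variableStep` declarations with spans.  WIG
#' coordinates are 1-based; values are stored 0-based internally, defined
#' exactly where the file gives values and undefined elsewhere.  A base
#' pair assigned a value twice is a format error.
#'
#' @param path file path.
#' @param genome a [genome_context()].
#' @param strict fail on unknown chromosomes (default FALSE: skip with a
#'   warning).
#' @return a `FunctionTrack`.
#' @export
read_wig <- function(path, genome, strict = FALSE) {
  gr <- rtracklayer::import(path, format = "wig")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  keep <- check_chroms(chroms, genome, strict)
  gr <- gr[keep]; chroms <- chroms[keep]
  if (!length(gr)) stop("no usable values in ", path)
  values <- list()
  for (ch in unique(chroms)) {
    sel <- gr[chroms == ch]
    L <- chrom_length(genome, ch)
    if (any(GenomicRanges::end(sel) > L))
      stop("WIG values beyond chromosome end on ", ch)
    v <- rep(NA_real_, L)
    s <- GenomicRanges::start(sel); e <- GenomicRanges::end(sel)
    sc <- sel$score
    for (i in seq_along(sel)) {
      idx <- s[i]:e[i]
      if (any(!is.na(v[idx])))
        stop("base pair defined twice in WIG on ", ch)
      v[idx] <- sc[i]
    }
    values[[ch]] <- v
  }
  function_track(values)
}

#' Write a function track as fixedStep WIG
#'
#' Each maximal defined run becomes a `fixedStep` block with `step=1`;
#' values round-trip bit-exactly through [read_wig()].
#'
#' @param track a `FunctionTrack` (or `IntensityTrack`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in track_chroms(track)) {
    v <- track$values[[ch]]
    def <- which(!is.na(v))
    if (!length(def)) next
    brk <- c(0L, which(diff(def) > 1L), length(def))
    for (j in seq_len(length(brk) - 1L)) {
      run <- def[(brk[j] + 1L):brk[j + 1L]]
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1", ch,
                         run[1L]), con)
      writeLines(format(v[run], scientific = FALSE, trim = TRUE,
                        digits = 15), con)
    }
  }
  invisible(path)
}

#' Write a results table as TSV
#'
#' One row per bin (or a single `"global"` row), tab-separated with a
#' `#`-prefixed header: bin id, coordinates, statistic, effect size, raw
#' and FDR-adjusted p, significance call, method, and MC sample count.
#' Rows keep genome order then bin start.
#'
#' @param result a `LocalResult` from [run_analysis()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_results_table <- function(result, path) {
  cols <- c("bin_id", "chrom", "start", "end", "statistic", "effect_size",
            "p", "p_fdr", "significant", "method", "n_mc")
  df <- as.data.frame(result)[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path file path.
#' @return data.frame with the table's columns.
#' @export
read_results_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  utils::read.table(path, sep = "\t", skip = 1L,
                    col.names = strsplit(header, "\t")[[1L]],
                    stringsAsFactors = FALSE, na.strings = "NA")
}
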