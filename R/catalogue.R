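# Registry of analyses by unordered track-type pair.  The five genomic
# types give 15 unordered pairs; the registry currently holds 13 analyses
# covering 8 of them, each motivated by a generic biological question
# ("do the points fall inside the segments more than expected?", ...).
# Information reduction (e.g. segments to their midpoints) opens further
# pairs dynamically; such matches are flagged "via coercion".

# reductions reachable from each type (reflexive closure added in use)
TYPE_REDUCTIONS <- list(UP = character(), MP = "UP", US = "UP",
                        MS = c("US", "MP", "UP"), "F" = character())

canonical_pair <- function(pair) {
  idx <- match(pair, TRACK_TYPES)
  if (anyNA(idx) || length(pair) != 2L)
    stop("a pair must be two of: ", paste(TRACK_TYPES, collapse = ", "))
  pair[order(idx)]
}

pair_key <- function(pair) paste(canonical_pair(pair), collapse = "-")

make_analysis <- function(id, pair, question, statistic, nulls,
                          alternatives, exact = FALSE) {
  structure(list(id = id, pair = canonical_pair(pair), question = question,
                 statistic = statistic, nulls = nulls,
                 alternatives = alternatives, exact = exact),
            class = "AnalysisDescriptor")
}

point_nulls <- list(t1 = c("uniform", "intensity"), t2 = "preserve_all")
seg_nulls <- c("permute_lengths_gaps", "uniform_position", "coverage_bp",
               "coverage_bernoulli")

ANALYSIS_REGISTRY <- list(
  make_analysis("point-proximity", c("UP", "UP"),
    "Do the T1 points fall closer to the T2 points than expected?",
    "mean_nearest_point_distance", point_nulls,
    c("less", "greater", "two-sided")),
  make_analysis("point-count-correlation", c("UP", "UP"),
    "Are the per-window counts of T1 and T2 points correlated?",
    "windowed_count_correlation", point_nulls,
    c("greater", "less", "two-sided")),
  make_analysis("inside-enrichment", c("UP", "US"),
    "Are the T1 points falling inside the T2 segments more than expected by chance?",
    "points_in_segments",
    list(t1 = c("uniform", "intensity", "preserve_all"),
         t2 = c("preserve_all", seg_nulls)),
    c("greater", "less", "two-sided"), exact = TRUE),
  make_analysis("border-accumulation", c("UP", "US"),
    "Do the points accumulate more at the borders of the segments, instead of being spread evenly within?",
    "border_affinity",
    list(t1 = c("uniform", "intensity"), t2 = "preserve_all"),
    c("less", "greater", "two-sided")),
  make_analysis("segment-proximity", c("UP", "US"),
    "Do the points fall closer to the segments than expected?",
    "mean_nearest_segment_distance",
    list(t1 = c("uniform", "intensity"),
         t2 = c("preserve_all", seg_nulls)),
    c("less", "greater", "two-sided")),
  make_analysis("count-mark-correlation", c("UP", "MS"),
    "Are the numbers of T1 points inside T2 segments correlated with the T2 marks?",
    "count_vs_mark_tau",
    list(t1 = c("uniform", "intensity", "preserve_all"),
         t2 = c("preserve_all", "permute_marks")),
    c("greater", "less", "two-sided")),
  make_analysis("function-at-points", c("UP", "F"),
    "Is the T2 function higher at the T1 points than elsewhere?",
    "mean_function_at_points", point_nulls,
    c("greater", "less", "two-sided")),
  make_analysis("overlap-enrichment", c("US", "US"),
    "Are the T1 segments overlapping the T2 segments more than expected by chance?",
    "bp_overlap",
    list(t1 = c("preserve_all", seg_nulls),
         t2 = c("preserve_all", seg_nulls)),
    c("greater", "less", "two-sided"), exact = TRUE),
  make_analysis("coverage-correlation", c("US", "US"),
    "Are the per-window coverages of the two segment tracks correlated?",
    "windowed_coverage_correlation",
    list(t1 = c("preserve_all", seg_nulls),
         t2 = c("preserve_all", seg_nulls)),
    c("greater", "less", "two-sided")),
  make_analysis("overlap-mark-difference", c("US", "MS"),
    "Do T2 segments overlapped by T1 carry different marks than the rest?",
    "overlap_mark_difference",
    list(t1 = c("preserve_all", seg_nulls),
         t2 = c("preserve_all", "permute_marks")),
    c("two-sided", "greater", "less")),
  make_analysis("function-in-segments", c("US", "F"),
    "Is the T2 function higher inside the T1 segments than outside?",
    "function_in_segments_difference",
    list(t1 = seg_nulls, t2 = "preserve_all"),
    c("greater", "less", "two-sided")),
  make_analysis("function-correlation", c("F", "F"),
    "Are the two functions correlated along the genome?",
    "function_correlation", list(t1 = "preserve_all", t2 = "preserve_all"),
    c("greater", "less", "two-sided")),
  make_analysis("function-mean-difference", c("F", "F"),
    "Is the first function on average higher than the second?",
    "function_mean_difference",
    list(t1 = "preserve_all", t2 = "preserve_all"),
    c("greater", "less", "two-sided"))
)
names(ANALYSIS_REGISTRY) <-
  vapply(ANALYSIS_REGISTRY, `[[`, character(1L), "id")

#' All unordered pairs of genomic types
#'
#' The five types give `C(5,2) + 5 = 15` unordered pairs (10 distinct-type
#' and 5 same-type).
#'
#' @return list of 15 character vectors of length 2.
#' @export
list_type_pairs <- function() {
  out <- list()
  for (i in seq_along(TRACK_TYPES))
    for (j in i:length(TRACK_TYPES))
      out[[length(out) + 1L]] <- c(TRACK_TYPES[i], TRACK_TYPES[j])
  out
}

#' Analyses registered for a type pair
#'
#' Looks up the analyses valid for an unordered pair of genomic types.
#' With `include_coercions = TRUE` the lookup also surfaces analyses
#' reachable by information-reducing the query types (e.g. an (MS, US)
#' query surfaces the (US, US) analyses via the MS-to-US reduction); such
#' hits carry `via_coercion = TRUE`.
#'
#' @param pair character vector of two type symbols (order irrelevant).
#' @param include_coercions also search pairs reachable by reduction.
#' @return list of `AnalysisDescriptor`s (possibly empty).
#' @export
analyses_for <- function(pair, include_coercions = FALSE) {
  pair <- canonical_pair(pair)
  direct <- Filter(function(a) identical(a$pair, pair), ANALYSIS_REGISTRY)
  direct <- lapply(direct, function(a) { a$via_coercion <- FALSE; a })
  if (!include_coercions) return(unname(direct))
  reach1 <- c(pair[1L], TYPE_REDUCTIONS[[pair[1L]]])
  reach2 <- c(pair[2L], TYPE_REDUCTIONS[[pair[2L]]])
  seen <- pair_key(pair)
  out <- direct
  for (t1 in reach1) for (t2 in reach2) {
    key <- pair_key(c(t1, t2))
    if (key %in% seen) next
    seen <- c(seen, key)
    hits <- Filter(function(a) identical(a$pair, canonical_pair(c(t1, t2))),
                   ANALYSIS_REGISTRY)
    out <- c(out, lapply(hits, function(a) { a$via_coercion <- TRUE; a }))
  }
  unname(out)
}

#' Catalogue conformance counts
#'
#' @return list with `n_analyses` (registered analyses) and
#'   `n_covered_pairs` (type pairs with at least one analysis).
#' @export
catalogue_summary <- function() {
  keys <- vapply(ANALYSIS_REGISTRY, function(a) pair_key(a$pair),
                 character(1L))
  list(n_analyses = length(ANALYSIS_REGISTRY),
       n_covered_pairs = length(unique(keys)))
}

#' The catalogue as a data frame
#'
#' One row per registered analysis: id, type pair, question, statistic,
#' alternatives.  Backs the `catalogue` CLI subcommand.
#'
#' @return data.frame.
#' @export
catalogue_table <- function() {
  do.call(rbind, lapply(ANALYSIS_REGISTRY, function(a)
    data.frame(id = a$id, pair = pair_key(a$pair), question = a$question,
               statistic = a$statistic,
               alternatives = paste(a$alternatives, collapse = ","),
               exact_null_available = a$exact,
               stringsAsFactors = FALSE))) -> df
  rownames(df) <- NULL
  df
}

#' Fetch one analysis descriptor by id
#' @param id analysis id (see [catalogue_table()]).
#' @return an `AnalysisDescriptor`.
#' @export
get_analysis <- function(id) {
  a <- ANALYSIS_REGISTRY[[id]]
  if (is.null(a))
    stop("unknown analysis '", id, "'; see catalogue_table()")
  a
}
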