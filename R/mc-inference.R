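# Turning a statistic and a null model into p-values: exact, asymptotic,
# standard Monte Carlo, or sequential Monte Carlo; run globally or per bin
# with Benjamini-Hochberg FDR across the tested bins.

new_test_result <- function(statistic, effect_size, p, method, n_samples,
                            alternative, null_mean = NA_real_,
                            null_sd = NA_real_) {
  structure(list(statistic = statistic, effect_size = effect_size, p = p,
                 method = method, n_samples = n_samples,
                 alternative = alternative, null_mean = null_mean,
                 null_sd = null_sd),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat("TestResult: statistic =", format(x$statistic),
      " effect =", format(x$effect_size),
      " p =", format(x$p), paste0("(", x$method,
      if (!is.na(x$n_samples)) paste0(", n = ", x$n_samples), ")"),
      " alternative =", x$alternative, "\n")
  invisible(x)
}

#' Exact binomial tail p-value
#'
#' Exact test for a count that is Binomial(n, p0) under the null, as for
#' the points-in-segments statistic when points are randomized uniformly
#' (p0 = segment coverage fraction) or segments per-bp Bernoulli
#' (p0 = covered fraction).  Effect size is observed over expected,
#' `observed / (n * p0)`.
#'
#' @param observed observed count, `0 <= observed <= n`.
#' @param n number of trials.
#' @param p0 null success probability.
#' @param alternative `"greater"`, `"less"` or `"two-sided"` (doubled
#'   one-sided, capped at 1).
#' @return a `TestResult` with method `"exact"`.
#' @examples
#' exact_binomial_p(10, 10, 0.5, "greater")$p  # 0.5^10
#' @export
exact_binomial_p <- function(observed, n, p0,
                             alternative = c("greater", "less",
                                             "two-sided")) {
  alternative <- match.arg(alternative)
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (observed < 0 || observed > n) stop("observed must lie in [0, n]")
  pg <- stats::pbinom(observed - 1, n, p0, lower.tail = FALSE)
  pl <- stats::pbinom(observed, n, p0)
  p <- switch(alternative, greater = pg, less = pl,
              "two-sided" = min(1, 2 * min(pg, pl)))
  eff <- if (n > 0 && p0 > 0) observed / (n * p0) else NA_real_
  new_test_result(observed, eff, p, "exact", NA_integer_, alternative,
                  null_mean = n * p0, null_sd = sqrt(n * p0 * (1 - p0)))
}

# effect size relative to the null distribution of the statistic:
# observed / expected for positive-mean statistics, else standardized
relative_effect <- function(obs, null_mean, null_sd) {
  if (!is.finite(null_mean)) return(NA_real_)
  if (null_mean > 0 && obs >= 0) return(obs / null_mean)
  if (is.finite(null_sd) && null_sd > 0) return((obs - null_mean) / null_sd)
  NA_real_
}

mc_p_from_counts <- function(r_ge, r_le, n, alternative) {
  switch(alternative,
         greater = (r_ge + 1) / (n + 1),
         less = (r_le + 1) / (n + 1),
         "two-sided" = min(1, 2 * min((r_ge + 1) / (n + 1),
                                      (r_le + 1) / (n + 1))))
}

#' Standard Monte Carlo p-value
#'
#' Draws `n_samples` joint replicates of the track pair from the
#' randomizer, recomputes the statistic on each, and estimates
#' `p = (r + 1) / (n_samples + 1)` where `r` counts replicates with
#' statistic at least the observed value (mirrored for `"less"`;
#' two-sided doubles the smaller tail).  The add-one estimator guarantees
#' a valid, never-zero p-value, so `p >= 1 / (n_samples + 1)`.
#'
#' @param statistic_fn `function(t1, t2)` returning a scalar.
#' @param t1,t2 observed (clipped) tracks.
#' @param randomizer a [build_randomizer()] closure.
#' @param bin list with `chrom`, `start`, `end` (randomization scope).
#' @param n_samples number of Monte Carlo replicates.
#' @param alternative `"greater"`, `"less"` or `"two-sided"`.
#' @param seed optional integer seed (set before sampling).
#' @return a `TestResult` with method `"mc"`.
#' @export
mc_p <- function(statistic_fn, t1, t2, randomizer, bin, n_samples = 999L,
                 alternative = c("greater", "less", "two-sided"),
                 seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic_fn(t1, t2)
  if (is.na(obs)) stop("statistic undefined on the observed data")
  reps <- vapply(seq_len(n_samples), function(i) {
    r <- randomizer(t1, t2, bin)
    statistic_fn(r$t1, r$t2)
  }, numeric(1L))
  reps_ok <- reps[!is.na(reps)]
  n <- length(reps_ok)
  if (n == 0L) stop("statistic undefined on every replicate")
  p <- mc_p_from_counts(sum(reps_ok >= obs), sum(reps_ok <= obs), n,
                        alternative)
  new_test_result(obs, relative_effect(obs, mean(reps_ok),
                                       stats::sd(reps_ok)),
                  p, "mc", n, alternative,
                  null_mean = mean(reps_ok), null_sd = stats::sd(reps_ok))
}

#' Sequential Monte Carlo p-value
#'
#' Samples replicates until the observed statistic has been exceeded
#' `k_exceed` times (in the tail of the chosen alternative), or until
#' `max_samples` replicates, whichever comes first; then
#' `p = (r + 1) / (n + 1)`.  Large p-values stop after about `k_exceed`
#' draws, while small p-values get the full `max_samples`, giving better
#' estimates of small p-values at reduced overall cost.  The smallest
#' attainable p is `1 / (max_samples + 1)`.
#'
#' @inheritParams mc_p
#' @param k_exceed stop once the tail count reaches this (default 20).
#' @param max_samples hard cap on replicates.
#' @return a `TestResult` with method `"sequential_mc"`.
#' @export
sequential_mc_p <- function(statistic_fn, t1, t2, randomizer, bin,
                            k_exceed = 20L, max_samples = 999L,
                            alternative = c("greater", "less",
                                            "two-sided"),
                            seed = NULL) {
  alternative <- match.arg(alternative)
  if (k_exceed < 1L) stop("k_exceed must be >= 1")
  if (max_samples < k_exceed) stop("max_samples must be >= k_exceed")
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic_fn(t1, t2)
  if (is.na(obs)) stop("statistic undefined on the observed data")
  r_ge <- 0L; r_le <- 0L; n <- 0L
  sum_s <- 0; sum_s2 <- 0
  tail_count <- function() switch(alternative, greater = r_ge,
                                  less = r_le,
                                  "two-sided" = min(r_ge, r_le))
  while (n < max_samples && tail_count() < k_exceed) {
    r <- randomizer(t1, t2, bin)
    s <- statistic_fn(r$t1, r$t2)
    if (is.na(s)) next
    n <- n + 1L
    if (s >= obs) r_ge <- r_ge + 1L
    if (s <= obs) r_le <- r_le + 1L
    sum_s <- sum_s + s; sum_s2 <- sum_s2 + s^2
  }
  if (n == 0L) stop("statistic undefined on every replicate")
  p <- mc_p_from_counts(r_ge, r_le, n, alternative)
  null_mean <- sum_s / n
  null_sd <- if (n > 1L) sqrt(max(0, (sum_s2 - n * null_mean^2) / (n - 1)))
             else NA_real_
  new_test_result(obs, relative_effect(obs, null_mean, null_sd), p,
                  "sequential_mc", n, alternative,
                  null_mean = null_mean, null_sd = null_sd)
}

#' Recommended Monte Carlo sample count
#'
#' At least two to five times the number of tests is needed for the FDR
#' adjustment to resolve the relevant p-values; the default recommends
#' five times the number of tests with a floor of 1,000 samples.
#'
#' @param n_tests number of tests (bins) sharing the FDR correction.
#' @return recommended number of MC samples (always `>= 2 * n_tests`).
#' @export
recommend_mc_samples <- function(n_tests) {
  if (n_tests < 1L) stop("n_tests must be >= 1")
  max(1000L, 5L * as.integer(n_tests))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone enforced) and the significance
#' calls at rate `q` (default 10%, the conventional cutoff for per-bin
#' genome scans).
#'
#' @param pvalues raw p-values in (0, 1].
#' @param q FDR level.
#' @return list with `adjusted` (same length) and `calls` (logical,
#'   `adjusted <= q`).
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  if (!length(pvalues)) return(list(adjusted = numeric(),
                                    calls = logical()))
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, calls = !is.na(adjusted) & adjusted <= q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve a statistic id to function(t1, t2) for a given bin
statistic_closure <- function(statistic_id, bin, genome, params = list()) {
  region <- list(chrom = bin$chrom, start = bin$start, end = bin$end)
  switch(statistic_id,
    mean_nearest_point_distance = function(t1, t2)
      mean_nearest_point_distance(t1, t2),
    windowed_count_correlation = ,
    windowed_coverage_correlation = function(t1, t2)
      windowed_correlation(t1, t2, region,
                           n_windows = params$n_windows %||% 10L),
    points_in_segments = function(t1, t2) points_in_segments(t1, t2),
    border_affinity = function(t1, t2) border_affinity(t1, t2),
    mean_nearest_segment_distance = function(t1, t2)
      mean_nearest_segment_distance(t1, t2),
    count_vs_mark_tau = function(t1, t2)
      count_vs_mark_tau(t1, t2, flank = params$flank %||% 0,
                        anchor = params$anchor %||% "segment"),
    mean_function_at_points = function(t1, t2)
      suppressMessages(mean_function_at_points(t2, t1)),
    bp_overlap = function(t1, t2) bp_overlap(t1, t2),
    overlap_mark_difference = function(t1, t2)
      marks_overlap_split(t1, t2)$difference,
    function_in_segments_difference = function(t1, t2)
      function_in_segments(t2, t1)$difference,
    function_correlation = function(t1, t2)
      function_correlation(t1, t2, method = params$method %||% "kendall"),
    function_mean_difference = function(t1, t2)
      mean_function_difference(t1, t2),
    stop("unknown statistic id: ", statistic_id))
}

# vectors behind tau statistics (for the asymptotic method), or NULL
tau_vectors <- function(statistic_id, t1, t2, bin, params = list()) {
  region <- list(chrom = bin$chrom, start = bin$start, end = bin$end)
  switch(statistic_id,
    windowed_count_correlation = ,
    windowed_coverage_correlation =
      window_summaries(t1, t2, region, params$n_windows %||% 10L),
    count_vs_mark_tau =
      count_mark_vectors(t1, t2, params$flank %||% 0,
                         params$anchor %||% "segment"),
    function_correlation = joint_function_values(t1, t2),
    NULL)
}

# exact binomial parameterization for the (analysis, null) pair, or NULL
exact_parameters <- function(analysis, null, t1, t2, bin, genome) {
  B <- bin$end - bin$start
  if (analysis$statistic == "points_in_segments") {
    n_pts <- length(t1$positions[[bin$chrom]])
    if (null$t1 == "uniform" && null$t2 == "preserve_all") {
      p0 <- coverage_fraction(t2, bin, genome)
      return(list(observed = points_in_segments(t1, t2), n = n_pts,
                  p0 = p0))
    }
    if (null$t1 == "preserve_all" && null$t2 == "coverage_bernoulli") {
      m <- t2$segments[[bin$chrom]]
      k <- if (is.null(m)) 0 else sum(m[, 2L] - m[, 1L])
      return(list(observed = points_in_segments(t1, t2), n = n_pts,
                  p0 = k / B))
    }
  }
  if (analysis$statistic == "bp_overlap") {
    one_bernoulli <- (null$t1 == "coverage_bernoulli" &&
                      null$t2 == "preserve_all") ||
                     (null$t2 == "coverage_bernoulli" &&
                      null$t1 == "preserve_all")
    if (one_bernoulli) {
      fixed <- if (null$t1 == "preserve_all") t1 else t2
      rand <- if (null$t1 == "preserve_all") t2 else t1
      mf <- fixed$segments[[bin$chrom]]; mr <- rand$segments[[bin$chrom]]
      kf <- if (is.null(mf)) 0 else sum(mf[, 2L] - mf[, 1L])
      kr <- if (is.null(mr)) 0 else sum(mr[, 2L] - mr[, 1L])
      return(list(observed = bp_overlap(t1, t2), n = kf, p0 = kr / B))
    }
  }
  NULL
}

# arrange/coerce the given tracks to the analysis's canonical type order
match_tracks_to_analysis <- function(analysis, t1, t2) {
  types <- c(infer_type(t1), infer_type(t2))
  want <- analysis$pair
  reachable <- function(from, to)
    from == to || to %in% TYPE_REDUCTIONS[[from]]
  fits <- function(a, b) reachable(types[a], want[1L]) &&
    reachable(types[b], want[2L])
  if (fits(1L, 2L)) {
    list(t1 = coerce_track(t1, want[1L]), t2 = coerce_track(t2, want[2L]))
  } else if (fits(2L, 1L)) {
    list(t1 = coerce_track(t2, want[1L]), t2 = coerce_track(t1, want[2L]))
  } else {
    stop("tracks of types (", types[1L], ", ", types[2L],
         ") cannot serve analysis '", analysis$id, "' (needs ",
         pair_key(want), ")")
  }
}

check_null_admissible <- function(analysis, null) {
  if (!null$t1 %in% analysis$nulls$t1)
    stop("null rule '", null$t1, "' for track 1 is not admissible for '",
         analysis$id, "' (allowed: ",
         paste(analysis$nulls$t1, collapse = ", "), ")")
  if (!null$t2 %in% analysis$nulls$t2)
    stop("null rule '", null$t2, "' for track 2 is not admissible for '",
         analysis$id, "' (allowed: ",
         paste(analysis$nulls$t2, collapse = ", "), ")")
}

# elements of a track inside the bin (for the sufficiency rule)
elements_in_bin <- function(track, bin) {
  type <- infer_type(track)
  ch <- as.character(bin$chrom)
  if (type %in% c("UP", "MP")) {
    p <- track$positions[[ch]]
    if (is.null(p)) 0L else sum(p >= bin$start & p < bin$end)
  } else if (type %in% c("US", "MS")) {
    m <- track$segments[[ch]]
    if (is.null(m)) 0L else sum(pmax(m[, 1L], bin$start) <
                                pmin(m[, 2L], bin$end))
  } else {
    v <- track$values[[ch]]
    if (is.null(v)) 0L
    else sum(!is.na(v[seq.int(bin$start + 1L, min(length(v), bin$end))]))
  }
}

# one bin's test, or a reason string when the bin cannot be tested
test_one_bin <- function(analysis, t1, t2, null, bin, genome, method,
                         mc, alternative, min_elements, params) {
  c1 <- clip_to_bin(t1, bin); c2 <- clip_to_bin(t2, bin)
  randomized <- c(null$t1, null$t2) != "preserve_all"
  for (i in which(randomized)) {
    tr <- if (i == 1L) c1 else c2
    if (elements_in_bin(tr, bin) < min_elements)
      return(paste0("track ", i, " has fewer than ", min_elements,
                    " elements in the bin"))
  }
  stat_fn <- statistic_closure(analysis$statistic, bin, genome, params)
  obs <- tryCatch(stat_fn(c1, c2), error = function(e) NA_real_)
  if (is.na(obs)) return("statistic undefined in the bin")

  if (method == "auto") {
    ep <- exact_parameters(analysis, null, c1, c2, bin, genome)
    if (!is.null(ep)) method <- "exact"
    else if (all(!randomized) &&
             !is.null(tau_vectors(analysis$statistic, c1, c2, bin, params)))
      method <- "asymptotic"
    else method <- if (isTRUE(mc$sequential)) "sequential_mc" else "mc"
  }
  switch(method,
    exact = {
      ep <- exact_parameters(analysis, null, c1, c2, bin, genome)
      if (is.null(ep))
        stop("no exact method for analysis '", analysis$id,
             "' under this null")
      exact_binomial_p(ep$observed, ep$n, ep$p0, alternative)
    },
    asymptotic = {
      v <- tau_vectors(analysis$statistic, c1, c2, bin, params)
      if (is.null(v)) stop("no asymptotic method for '", analysis$id, "'")
      alt <- switch(alternative, "two-sided" = "two.sided", alternative)
      ct <- suppressWarnings(stats::cor.test(v$x, v$y, method = "kendall",
                                             alternative = alt))
      new_test_result(unname(ct$estimate), unname(ct$estimate),
                      ct$p.value, "asymptotic", NA_integer_, alternative)
    },
    mc = mc_p(stat_fn, c1, c2, build_randomizer(null, genome), bin,
              n_samples = mc$n %||% 999L, alternative = alternative),
    sequential_mc = sequential_mc_p(stat_fn, c1, c2,
                                    build_randomizer(null, genome), bin,
                                    k_exceed = mc$k %||% 20L,
                                    max_samples = mc$max %||%
                                      (mc$n %||% 999L),
                                    alternative = alternative),
    stop("unknown method: ", method))
}

#' Run an analysis globally or per bin
#'
#' Executes one catalogue analysis on a track pair under a null model,
#' either globally (one test on a region) or locally (one test per bin
#' with BH-FDR correction across the tested bins).  The exact method is
#' used where the analysis/null pair admits it, the asymptotic tau
#' approximation where no track is randomized and the statistic is a
#' correlation, and (sequential) Monte Carlo otherwise.  Bins where a
#' randomized track has fewer than `min_elements` elements, or where the
#' statistic is undefined, are flagged untested and excluded from the FDR
#' family.  Randomization is confined to each bin (local) or the whole
#' region (global).  Reproducibility: per-bin RNG substreams are seeded
#' `seed + bin index`, so results are independent of bin evaluation order
#' and bit-identical across runs with the same seed.
#'
#' @param analysis an `AnalysisDescriptor` or its id string.
#' @param t1,t2 tracks (coerced/swapped to the analysis's type pair).
#' @param genome a [genome_context()].
#' @param null a [null_model_spec()].
#' @param scope a `RegionSpec` (global test) or a [make_bins()]
#'   `BinPartition` (local analysis).
#' @param alternative `"greater"`, `"less"` or `"two-sided"`; default the
#'   analysis's first registered alternative.
#' @param method `"auto"` (default), `"exact"`, `"asymptotic"`, `"mc"`,
#'   or `"sequential_mc"`.
#' @param mc list of MC settings: `n` (samples), `sequential` (logical),
#'   `k` (sequential stop count), `max` (sequential cap).
#' @param fdr_q FDR level for local analyses (default 0.10).
#' @param min_elements per-bin sufficiency threshold (default 5).
#' @param seed integer seed.
#' @param params statistic parameters (e.g. `n_windows`, `flank`).
#' @return a `LocalResult`: data.frame (one row per bin, or a single
#'   `"global"` row) with columns `bin_id`, `chrom`, `start`, `end`,
#'   `statistic`, `effect_size`, `p`, `p_fdr`, `significant`, `method`,
#'   `n_mc`, `untested`, `reason`; metadata in attributes.
#' @export
run_analysis <- function(analysis, t1, t2, genome, null, scope,
                         alternative = NULL, method = "auto",
                         mc = list(), fdr_q = 0.10, min_elements = 5L,
                         seed = 1L, params = list()) {
  if (is.character(analysis)) analysis <- get_analysis(analysis)
  alternative <- alternative %||% analysis$alternatives[1L]
  alternative <- match.arg(alternative, c("greater", "less", "two-sided"))
  check_null_admissible(analysis, null)
  tr <- match_tracks_to_analysis(analysis, t1, t2)

  if (inherits(scope, "BinPartition")) {
    bins <- scope
  } else if (inherits(scope, "whole_genome")) {
    stop("whole-genome global analysis: pass a BinPartition, or a region",
         " on one chromosome")
  } else {
    bins <- data.frame(bin_id = "global", chrom = scope$chrom,
                       start = scope$start, end = scope$end,
                       stringsAsFactors = FALSE)
  }
  rows <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    bin <- as.list(bins[i, ])
    set.seed(as.integer(seed) + i)
    res <- test_one_bin(analysis, tr$t1, tr$t2, null, bin, genome, method,
                        mc, alternative, min_elements, params)
    if (is.character(res)) {
      rows[[i]] <- data.frame(bin_id = bin$bin_id, chrom = bin$chrom,
                              start = bin$start, end = bin$end,
                              statistic = NA_real_,
                              effect_size = NA_real_, p = NA_real_,
                              method = NA_character_, n_mc = NA_integer_,
                              untested = TRUE, reason = res,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(bin_id = bin$bin_id, chrom = bin$chrom,
                              start = bin$start, end = bin$end,
                              statistic = res$statistic,
                              effect_size = res$effect_size, p = res$p,
                              method = res$method,
                              n_mc = res$n_samples %||% NA_integer_,
                              untested = FALSE, reason = "",
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$p_fdr <- NA_real_
  df$significant <- NA
  tested <- !df$untested
  if (any(tested)) {
    adj <- bh_fdr(df$p[tested], q = fdr_q)
    df$p_fdr[tested] <- adj$adjusted
    df$significant[tested] <- adj$calls
  }
  df <- df[, c("bin_id", "chrom", "start", "end", "statistic",
               "effect_size", "p", "p_fdr", "significant", "method",
               "n_mc", "untested", "reason")]
  structure(df, class = c("LocalResult", "data.frame"),
            analysis = analysis$id, alternative = alternative,
            null = c(t1 = null$t1, t2 = null$t2), fdr_q = fdr_q,
            seed = seed)
}

#' One-line verdict for a result table
#'
#' `"Significant in k of n tested bin(s)"`, or the guarded
#' `"No support from data for this conclusion in any bin"` when no call
#' survives the FDR correction.
#'
#' @param result a `LocalResult` from [run_analysis()].
#' @return character summary.
#' @export
summarize_result <- function(result) {
  tested <- !result$untested
  n_sig <- sum(result$significant[tested], na.rm = TRUE)
  if (!any(tested)) return("No bin had sufficient data to be tested")
  if (n_sig == 0L)
    return("No support from data for this conclusion in any bin")
  sprintf("Significant in %d of %d tested bin(s) at FDR %g%%", n_sig,
          sum(tested), 100 * attr(result, "fdr_q"))
}
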