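# Every statistic is checked against a literal brute-force oracle on
# random small instances in test-acceptance.R; here the documented
# examples, closed forms, and structural invariances.

test_that("bp_overlap matches hand-computed cases and is symmetric", {
  a <- segment_track(list(chrT = cbind(0, 10)))
  b <- segment_track(list(chrT = cbind(5, 15)))
  expect_equal(bp_overlap(a, b), 5)
  expect_equal(bp_overlap(b, a), 5)
  c2 <- segment_track(list(chrT = cbind(c(0, 10), c(5, 20))))
  d <- segment_track(list(chrT = cbind(3, 12)))
  expect_equal(bp_overlap(c2, d), 4)  # [3,5) + [10,12)
  disjoint <- segment_track(list(chrT = cbind(50, 60)))
  expect_equal(bp_overlap(a, disjoint), 0)
})

test_that("points_in_segments honours the half-open convention", {
  pts <- point_track(list(chrT = c(1, 7, 12)))
  segs <- segment_track(list(chrT = cbind(c(0, 10), c(5, 20))))
  expect_equal(points_in_segments(pts, segs), 2L)
  at_end <- point_track(list(chrT = 5))
  expect_equal(points_in_segments(at_end,
                                  segment_track(list(chrT = cbind(0, 5)))),
               0L)
  empty <- segment_track(list(chrT = NULL))
  expect_equal(points_in_segments(pts, empty), 0L)
})

test_that("coverage_fraction uses the defined-region denominator", {
  g <- tiny_genome(10)
  reg <- list(chrom = "chrT", start = 0, end = 10)
  expect_equal(coverage_fraction(segment_track(list(chrT = cbind(0, 5))),
                                 reg, g), 0.5)
  expect_equal(coverage_fraction(segment_track(list(chrT = cbind(0, 10))),
                                 reg, g), 1.0)
  gm <- tiny_genome(10, mask = cbind(0, 5))
  expect_equal(coverage_fraction(segment_track(list(chrT = cbind(0, 5))),
                                 reg, gm), 1.0)
})

test_that("count_vs_mark_tau is +/-1 on perfectly ordered data", {
  # three segments, counts 1, 2, 3 by construction
  pts <- point_track(list(chrT = c(0, 10, 11, 20, 21, 22)))
  segs <- list(chrT = cbind(c(0, 10, 20), c(5, 15, 25)))
  up_marks <- marked_segment_track(segs, list(chrT = c(10, 20, 30)))
  expect_equal(count_vs_mark_tau(pts, up_marks), 1)
  down_marks <- marked_segment_track(segs, list(chrT = c(30, 20, 10)))
  expect_equal(count_vs_mark_tau(pts, down_marks), -1)
})

test_that("tau-b equals the O(n^2) concordance oracle under heavy ties", {
  set.seed(21)
  for (i in 1:25) {
    x <- rpois(20, 2)
    y <- rpois(20, 3)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(trackperm:::kendall_tau_b(x, y), oracle_tau_b(x, y))
  }
})

test_that("mean_function_at_points looks up per-bp values", {
  f <- function_track(list(chrT = {
    v <- rep(NA_real_, 30); v[11] <- 1; v[21] <- 3; v
  }))
  pts <- point_track(list(chrT = c(10, 20)))
  expect_equal(mean_function_at_points(f, pts), 2)
  const <- function_track(list(chrT = rep(7, 30)))
  expect_equal(mean_function_at_points(const, pts), 7)
  # masked points are excluded with a message, not an error
  part <- point_track(list(chrT = c(5, 10)))
  expect_message(got <- mean_function_at_points(f, part), "excluded")
  expect_equal(got, 1)
})

test_that("border_affinity closed forms hold", {
  segs <- segment_track(list(chrT = cbind(10, 21)))  # odd length 11
  expect_equal(border_affinity(point_track(list(chrT = 10)), segs), 0)
  len <- 11
  expect_equal(border_affinity(point_track(list(chrT = 15)), segs),
               (len - 1) / (2 * len))
  # uniform placement over all in-segment positions: 0.25 - O(1/len)
  all_pos <- point_track(list(chrT = 10:20))
  enum <- mean(pmin(0:10, 10:0) / 11)
  expect_equal(border_affinity(all_pos, segs), enum)
  expect_lt(abs(enum - 0.25), 1 / len)
  none <- point_track(list(chrT = 5))
  expect_true(is.na(border_affinity(none, segs)))
})

test_that("nearest-distance statistics match simple geometry", {
  segs <- segment_track(list(chrT = cbind(10, 20)))
  expect_equal(mean_nearest_segment_distance(
    point_track(list(chrT = 7)), segs), 3)
  expect_equal(mean_nearest_segment_distance(
    point_track(list(chrT = 15)), segs), 0)
  expect_equal(mean_nearest_segment_distance(
    point_track(list(chrT = 25)), segs), 6)  # to last covered bp 19
  expect_equal(mean_nearest_point_distance(
    point_track(list(chrT = c(0, 10))),
    point_track(list(chrT = 4))), mean(c(4, 6)))
})

test_that("marks_overlap_split partitions by intersection", {
  a <- segment_track(list(chrT = cbind(0, 10)))
  b <- marked_segment_track(list(chrT = cbind(c(5, 50), c(15, 60))),
                            list(chrT = c(1, 3)))
  got <- marks_overlap_split(a, b)
  expect_equal(got$mean_overlap, 1)
  expect_equal(got$mean_rest, 3)
  expect_equal(got$difference, -2)
  all_in <- marked_segment_track(list(chrT = cbind(2, 8)),
                                 list(chrT = 5))
  expect_true(is.na(marks_overlap_split(a, all_in)$difference))
})

test_that("function correlation and difference behave on joint support", {
  v <- c(NA, 1, 2, 3, 4, NA)
  f <- function_track(list(chrT = v))
  expect_equal(function_correlation(f, f), 1)
  neg <- function_track(list(chrT = -v))
  expect_equal(function_correlation(f, neg, method = "pearson"), -1)
  expect_equal(mean_function_difference(f, neg), 2 * mean(1:4))
  short <- function_track(list(chrT = c(NA, 5)))
  expect_true(is.na(function_correlation(f, short)))
  fis <- function_in_segments(f, segment_track(list(chrT = cbind(1, 3))))
  expect_equal(fis$mean_inside, mean(c(1, 2)))
  expect_equal(fis$mean_outside, mean(c(3, 4)))
  expect_equal(fis$difference, 1.5 - 3.5)
})

test_that("statistics are invariant under chromosome relabeling", {
  set.seed(31)
  pts <- rand_points(20, 500)
  segs <- rand_segments(500)
  relabel <- function(tr) { names(tr[[1]]) <- "chr9"; tr }
  expect_equal(points_in_segments(relabel(pts), relabel(segs)),
               points_in_segments(pts, segs))
  expect_equal(bp_overlap(relabel(segs), relabel(segs)),
               bp_overlap(segs, segs))
})

test_that("bin-additive statistics commute with clipping", {
  set.seed(32)
  g <- tiny_genome(600)
  bins <- make_bins(parse_region("chrT", g), 150, g)
  for (i in 1:10) {
    pts <- rand_points(30, 600)
    s1 <- rand_segments(600)
    s2 <- rand_segments(600)
    per_bin <- sapply(seq_len(nrow(bins)), function(j) {
      b <- as.list(bins[j, ])
      c(points_in_segments(clip_to_bin(pts, b), clip_to_bin(s1, b)),
        bp_overlap(clip_to_bin(s1, b), clip_to_bin(s2, b)))
    })
    expect_equal(sum(per_bin[1, ]), points_in_segments(pts, s1))
    expect_equal(sum(per_bin[2, ]), bp_overlap(s1, s2))
  }
})
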