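bin_of <- function(len) list(chrom = "chrT", start = 0, end = len)

test_that("lengths-and-gaps permutation conserves both multisets", {
  set.seed(41)
  bin <- bin_of(500)
  for (i in 1:30) {
    segs <- rand_segments(500)
    m <- segs$segments$chrT
    if (!nrow(m)) next
    lens <- unname(sort(m[, 2] - m[, 1]))
    gaps <- unname(sort(c(m[1, 1], if (nrow(m) > 1)
      m[-1, 1] - m[-nrow(m), 2], 500 - m[nrow(m), 2])))
    r <- randomize_segments_permute(segs, bin)
    rm_ <- r$segments$chrT
    expect_equal(unname(sort(rm_[, 2] - rm_[, 1])), lens)
    rgaps <- unname(sort(c(rm_[1, 1], if (nrow(rm_) > 1)
      rm_[-1, 1] - rm_[-nrow(rm_), 2], 500 - rm_[nrow(rm_), 2])))
    expect_equal(rgaps, gaps)
    expect_true(all(rm_[, 1] < rm_[, 2]))
    expect_true(all(rm_[-1, 1] >= rm_[-nrow(rm_), 2]) || nrow(rm_) == 1)
  }
})

test_that("a bin-filling segment is a fixed point of the permutation", {
  segs <- segment_track(list(chrT = cbind(0, 100)))
  r <- randomize_segments_permute(segs, bin_of(100))
  expect_equal(r$segments$chrT, cbind(start = 0, end = 100))
})

test_that("gap permutation is coarser than uniform placement", {
  # one segment [2,4) in a bin of 10: gaps {2,6}, so the start can only
  # be 2 or 6, each with probability 1/2 -- not uniform over 0..8
  set.seed(42)
  segs <- segment_track(list(chrT = cbind(2, 4)))
  starts <- replicate(4000,
    randomize_segments_permute(segs, bin_of(10))$segments$chrT[1, 1])
  tab <- table(starts)
  expect_setequal(as.numeric(names(tab)), c(2, 6))
  expect_gt(min(tab) / 4000, 0.45)
})

test_that("uniform placement puts a single segment uniformly", {
  set.seed(43)
  segs <- segment_track(list(chrT = cbind(0, 3)))
  bin <- bin_of(20)  # length 3 in 20 bp: starts 0..17
  starts <- replicate(10000,
    randomize_segments_uniform(segs, bin)$segments$chrT[1, 1])
  expect_setequal(sort(unique(starts)), 0:17)
  p <- chisq.test(table(factor(starts, levels = 0:17)))$p.value
  expect_gt(p, 0.01)
})

test_that("uniform placement keeps lengths, disjointness, and fits", {
  set.seed(44)
  bin <- bin_of(300)
  for (i in 1:30) {
    segs <- rand_segments(300)
    m <- segs$segments$chrT
    if (!nrow(m)) next
    r <- randomize_segments_uniform(segs, bin)$segments$chrT
    expect_equal(sort(r[, 2] - r[, 1]), sort(m[, 2] - m[, 1]))
    expect_true(all(r[, 1] >= 0) && all(r[, 2] <= 300))
    if (nrow(r) > 1) expect_true(all(r[-1, 1] >= r[-nrow(r), 2]))
  }
  # two touching segments that exactly fill the bin (built raw to keep
  # them unmerged): only their order can change
  full <- trackperm:::new_track(list(segments = list(
    chrT = cbind(start = c(0, 10), end = c(10, 30)))), "SegmentTrack")
  r <- randomize_segments_uniform(full, bin_of(30))$segments$chrT
  expect_equal(sum(r[, 2] - r[, 1]), 30)
  too_big <- segment_track(list(chrT = cbind(0, 50)))
  expect_error(randomize_segments_uniform(too_big, bin_of(30)), "exceeds")
})

test_that("coverage resampling conserves the covered-bp count exactly", {
  set.seed(45)
  bin <- bin_of(200)
  for (i in 1:20) {
    segs <- rand_segments(200)
    k <- sum(coverage_vector(segs, 200))
    r <- randomize_coverage_bp(segs, bin)
    expect_equal(sum(coverage_vector(r, 200)), k)
  }
  # k = bin length -> full cover; k = 0 -> empty
  full <- segment_track(list(chrT = cbind(0, 200)))
  expect_equal(randomize_coverage_bp(full, bin)$segments$chrT,
               cbind(start = 0, end = 200))
  empty <- clip_to_bin(segment_track(list(chrT = cbind(300, 400))),
                       bin_of(200))
  expect_equal(nrow(randomize_coverage_bp(empty, bin)$segments$chrT), 0L)
})

test_that("coverage resampling has uniform per-bp marginals", {
  set.seed(46)
  bin <- bin_of(50)
  segs <- segment_track(list(chrT = cbind(c(0, 30), c(10, 35))))  # k = 15
  hits <- numeric(50)
  n_draw <- 4000
  for (i in seq_len(n_draw))
    hits <- hits + coverage_vector(randomize_coverage_bp(segs, bin), 50)
  p_hat <- hits / n_draw
  se <- sqrt(0.3 * 0.7 / n_draw)
  expect_true(all(abs(p_hat - 15 / 50) < 5 * se))
})

test_that("uniform point randomization respects count, bounds and mask", {
  set.seed(47)
  g <- tiny_genome(100, mask = cbind(c(0, 60), c(40, 100)))
  bin <- bin_of(100)
  pts <- point_track(list(chrT = c(1, 5, 20, 65, 99)))
  for (i in 1:200) {
    r <- randomize_points_uniform(pts, bin, g)
    p <- r$positions$chrT
    expect_length(p, 5L)
    expect_equal(anyDuplicated(p), 0L)
    expect_true(all((p >= 0 & p < 40) | (p >= 60 & p < 100)))
  }
  # n equals the defined length: every defined position is returned
  gs <- tiny_genome(10, mask = cbind(2, 7))
  all_pts <- point_track(list(chrT = 2:6))
  r <- randomize_points_uniform(all_pts, bin_of(10), gs)
  expect_equal(r$positions$chrT, 2:6)
})

test_that("intensity-driven points follow the intensity support", {
  set.seed(48)
  g <- tiny_genome(100)
  bin <- bin_of(100)
  pts <- point_track(list(chrT = c(3, 50, 80)))
  v <- rep(0, 100); v[21:40] <- 2
  lam <- function_track(list(chrT = v))
  for (i in 1:50) {
    r <- randomize_points_intensity(pts, bin, lam, g)
    expect_true(all(r$positions$chrT >= 20 & r$positions$chrT < 40))
  }
  few <- function_track(list(chrT = c(1, 1, rep(0, 98))))
  expect_error(randomize_points_intensity(pts, bin, few, g),
               "fewer than n")
})

test_that("mark permutation preserves the mark multiset", {
  set.seed(49)
  ms <- marked_segment_track(list(chrT = cbind(seq(0, 90, 10),
                                               seq(5, 95, 10))),
                             list(chrT = rnorm(10)))
  r <- permute_marks(ms)
  expect_equal(sort(r$marks$chrT), sort(ms$marks$chrT))
  expect_equal(r$segments$chrT, ms$segments$chrT)
  single <- marked_point_track(list(chrT = 5), list(chrT = 3))
  expect_equal(permute_marks(single)$marks$chrT, 3)
  expect_error(permute_marks(point_track(list(chrT = 1))), "marked")
})

test_that("tau under mark permutation centers at zero", {
  set.seed(50)
  pts <- rand_points(60, 500)
  segs <- sim_segments(list(chrom = "chrT", start = 0, end = 500),
                       list(dist = "fixed", value = 10),
                       list(dist = "fixed", value = 10))
  ms <- sim_marked(segs, list(model = "independent", mean = 0, sd = 1))
  taus <- replicate(400, count_vs_mark_tau(pts, permute_marks(ms)))
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus)), 3 * se + 1e-12)
})

test_that("randomizer closures honour preservation and reproducibility", {
  set.seed(51)
  g <- tiny_genome(300)
  bin <- bin_of(300)
  pts <- rand_points(20, 300)
  segs <- rand_segments(300)
  identity_rand <- build_randomizer(null_model_spec("preserve_all",
                                                    "preserve_all"), g)
  r <- identity_rand(pts, segs, bin)
  expect_identical(r$t1, pts)
  expect_identical(r$t2, segs)
  both <- build_randomizer(null_model_spec("uniform",
                                           "permute_lengths_gaps"), g)
  set.seed(99); a <- both(pts, segs, bin)
  set.seed(99); b <- both(pts, segs, bin)
  expect_identical(a, b)  # same seed, bit-identical replicate
  set.seed(100); c2 <- both(pts, segs, bin)
  expect_false(identical(a$t1$positions$chrT, c2$t1$positions$chrT))
})

test_that("the segment-rule family spans rules x track scopes", {
  # three non-trivial segment rules applied to track a, b, or both
  rules <- c("permute_lengths_gaps", "uniform_position", "coverage_bp")
  g <- tiny_genome(200)
  bin <- bin_of(200)
  s1 <- rand_segments(200); s2 <- rand_segments(200)
  for (rule in rules) {
    for (scope in list(c(rule, "preserve_all"), c("preserve_all", rule),
                       c(rule, rule))) {
      spec <- null_model_spec(scope[1], scope[2])
      r <- build_randomizer(spec, g)(s1, s2, bin)
      if (scope[1] == "preserve_all") expect_identical(r$t1, s1)
      if (scope[2] == "preserve_all") expect_identical(r$t2, s2)
      expect_equal(infer_type(r$t1), "US")
      expect_equal(infer_type(r$t2), "US")
    }
  }
  expect_error(null_model_spec("no_such_rule", "preserve_all"), "unknown")
  expect_error(null_model_spec("intensity", "preserve_all"), "requires")
})
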