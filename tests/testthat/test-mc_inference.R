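test_that("exact binomial tails match closed forms", {
  expect_equal(exact_binomial_p(10, 10, 0.5, "greater")$p, 0.5^10)
  expect_equal(exact_binomial_p(0, 10, 0.5, "greater")$p, 1)
  expect_equal(exact_binomial_p(2, 3, 0.5, "greater")$p, 4 / 8)
  expect_equal(exact_binomial_p(2, 3, 0.5, "less")$p, 7 / 8)
  ts <- exact_binomial_p(9, 10, 0.5, "two-sided")
  expect_equal(ts$p, min(1, 2 * pbinom(8, 10, 0.5, lower.tail = FALSE)))
  # effect size is observed over expected
  expect_equal(exact_binomial_p(6, 10, 0.3, "greater")$effect_size, 2)
  expect_error(exact_binomial_p(5, 10, 1.5), "p0")
  expect_error(exact_binomial_p(11, 10, 0.5), "observed")
})

test_that("MC p-values use the add-one estimator with tie counting", {
  g <- tiny_genome(100)
  bin <- list(chrom = "chrT", start = 0, end = 100)
  pts <- point_track(list(chrT = c(5, 50)))
  segs <- segment_track(list(chrT = cbind(0, 60)))
  stat <- function(t1, t2) points_in_segments(t1, t2)
  # identity randomizer: every replicate ties the observation -> p = 1
  ident <- build_randomizer(null_model_spec("preserve_all",
                                            "preserve_all"), g)
  r <- mc_p(stat, pts, segs, ident, bin, n_samples = 99, seed = 1)
  expect_equal(r$p, 1)
  expect_equal(r$method, "mc")
  expect_equal(r$n_samples, 99L)
  # a constant statistic above all replicates: p = (0+1)/(99+1)
  fake_rand <- function(t1, t2, bin) list(t1 = point_track(list(
    chrT = c(70, 80))), t2 = t2)
  r2 <- mc_p(stat, pts, segs, fake_rand, bin, n_samples = 99, seed = 1)
  expect_equal(r2$p, 0.01)
  r3 <- mc_p(stat, pts, segs, fake_rand, bin, n_samples = 99, seed = 1,
             alternative = "less")
  expect_equal(r3$p, 1)
  expect_gte(r2$p, 1 / (99 + 1))
})

test_that("sequential MC stops by the exceedance rule", {
  g <- tiny_genome(100)
  bin <- list(chrom = "chrT", start = 0, end = 100)
  pts <- point_track(list(chrT = 5))
  segs <- segment_track(list(chrT = cbind(0, 60)))
  stat <- function(t1, t2) points_in_segments(t1, t2)
  ident <- build_randomizer(null_model_spec("preserve_all",
                                            "preserve_all"), g)
  # every replicate ties/exceeds: stop at n = k_exceed with p = 1
  r <- sequential_mc_p(stat, pts, segs, ident, bin, k_exceed = 20,
                       max_samples = 500, seed = 2)
  expect_equal(r$n_samples, 20L)
  expect_equal(r$p, 1)
  expect_equal(r$method, "sequential_mc")
  # no replicate ever reaches the observation: full max_samples, minimal p
  out_rand <- function(t1, t2, bin) list(t1 = point_track(list(
    chrT = 70)), t2 = t2)
  r2 <- sequential_mc_p(stat, pts, segs, out_rand, bin, k_exceed = 20,
                        max_samples = 200, seed = 3)
  expect_equal(r2$n_samples, 200L)
  expect_equal(r2$p, 1 / 201)
  expect_error(sequential_mc_p(stat, pts, segs, ident, bin, k_exceed = 0),
               "k_exceed")
})

test_that("MC sample-count guidance enforces the floor and multiplier", {
  expect_equal(recommend_mc_samples(19), 1000L)
  expect_equal(recommend_mc_samples(1), 1000L)
  expect_equal(recommend_mc_samples(500), 2500L)
  for (n in c(1, 10, 100, 1000))
    expect_gte(recommend_mc_samples(n), 2 * n)
})

test_that("BH adjustment matches hand computation and brute force", {
  got <- bh_fdr(c(0.01, 0.4), q = 0.1)
  expect_equal(got$adjusted, c(0.02, 0.4))
  expect_equal(got$calls, c(TRUE, FALSE))
  all_one <- bh_fdr(rep(1, 5), q = 0.1)
  expect_false(any(all_one$calls))
  expect_equal(bh_fdr(numeric())$adjusted, numeric())
  set.seed(81)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- bh_fdr(p, q = 0.1)
    expect_equal(got$adjusted, oracle_bh_adjusted(p))
    expect_equal(got$calls, oracle_bh_calls(p, 0.1))
    expect_true(all(got$adjusted >= p))
  }
  expect_error(bh_fdr(c(0, 0.5)), "p-values")
})

test_that("FDR calls are invariant to bin order", {
  set.seed(82)
  p <- runif(30)^2
  o <- sample(30)
  a <- bh_fdr(p, 0.1)
  b <- bh_fdr(p[o], 0.1)
  expect_equal(b$calls[order(o)], a$calls)
  expect_equal(b$adjusted[order(o)], a$adjusted)
})

test_that("single-bin local analysis equals the global analysis", {
  set.seed(83)
  g <- tiny_genome(1000)
  reg <- list(chrom = "chrT", start = 0, end = 1000)
  pts <- sim_points(reg, rate = 0.03)
  segs <- sim_segments(reg)
  null <- null_model_spec("permute_lengths_gaps", "preserve_all")
  other <- sim_markov_coverage(reg, 0.02, 0.9)
  bins1 <- make_bins(parse_region("chrT", g), 1000, g)
  local <- run_analysis("overlap-enrichment", segs, other, g, null,
                        bins1, mc = list(n = 49), seed = 9)
  global <- run_analysis("overlap-enrichment", segs, other, g, null,
                         parse_region("chrT", g), mc = list(n = 49),
                         seed = 9)
  expect_equal(local$p, global$p)
  expect_equal(local$statistic, global$statistic)
})

test_that("run_analysis is reproducible and flags sparse bins", {
  set.seed(84)
  g <- tiny_genome(2000)
  reg <- list(chrom = "chrT", start = 0, end = 2000)
  pts <- sim_points(reg, rate = 0.02)
  segs <- sim_segments(reg)
  null <- null_model_spec("uniform", "preserve_all")
  bins <- make_bins(parse_region("chrT", g), 500, g)
  a <- run_analysis("inside-enrichment", pts, segs, g, null, bins,
                    method = "mc", mc = list(n = 29), seed = 4)
  b <- run_analysis("inside-enrichment", pts, segs, g, null, bins,
                    method = "mc", mc = list(n = 29), seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # min_elements excludes sparse bins from testing and from the FDR family
  sparse <- point_track(list(chrT = c(1, 2, 3)))
  res <- run_analysis("inside-enrichment", sparse, segs, g, null, bins,
                      mc = list(n = 29), seed = 4, min_elements = 5)
  expect_true(all(res$untested))
  expect_match(summarize_result(res), "No bin had sufficient data")
})

test_that("inadmissible nulls and incompatible tracks fail fast", {
  g <- tiny_genome(100)
  pts <- point_track(list(chrT = c(1, 2)))
  f <- function_track(list(chrT = rep(1, 100)))
  expect_error(run_analysis("function-at-points", pts, f, g,
                            null_model_spec("coverage_bp",
                                            "preserve_all"),
                            parse_region("chrT", g)),
               "not admissible")
  segs <- segment_track(list(chrT = cbind(0, 10)))
  expect_error(run_analysis("function-correlation", pts, segs, g,
                            null_model_spec("preserve_all",
                                            "preserve_all"),
                            parse_region("chrT", g)),
               "cannot serve")
})

test_that("asymptotic tau method engages for conserved-track pairs", {
  set.seed(85)
  len <- 300
  g <- tiny_genome(len)
  v <- as.numeric(stats::filter(rnorm(len), rep(1 / 20, 20),
                                circular = TRUE))
  f1 <- function_track(list(chrT = v))
  f2 <- function_track(list(chrT = v + rnorm(len, sd = 0.1)))
  res <- run_analysis("function-correlation", f1, f2, g,
                      null_model_spec("preserve_all", "preserve_all"),
                      parse_region("chrT", g), alternative = "greater")
  expect_equal(res$method, "asymptotic")
  expect_lt(res$p, 0.01)
  expect_gt(res$statistic, 0.5)
})
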