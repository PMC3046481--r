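# Shared fixtures: random small tracks plus literal per-bp / per-element
# brute-force oracles, kept deliberately naive and independent of the
# package's vectorized implementations.

tiny_genome <- function(len = 1000, chrom = "chrT", mask = NULL) {
  genome_context(setNames(len, chrom),
                 defined_regions = if (!is.null(mask))
                   setNames(list(mask), chrom))
}

rand_points <- function(n, len, chrom = "chrT") {
  point_track(setNames(list(sort(sample.int(len, n) - 1)), chrom))
}

# random disjoint sorted segments inside [0, len)
rand_segments <- function(len, n_target = 8, chrom = "chrT") {
  covered <- sort(sample.int(len, min(len, max(2, rpois(1, n_target * 10)))))
  m <- NULL
  if (length(covered)) {
    brk <- c(0L, which(diff(covered) > 1L), length(covered))
    starts <- covered[brk[-length(brk)] + 1L] - 1L
    ends <- covered[brk[-1L]]
    m <- cbind(start = starts, end = ends)
  }
  segment_track(setNames(list(m), chrom))
}

rand_function <- function(len, chrom = "chrT", undef_frac = 0.1) {
  v <- rnorm(len)
  v[sample.int(len, floor(undef_frac * len))] <- NA
  function_track(setNames(list(v), chrom))
}

# per-bp coverage indicator of a single-chromosome segment track
coverage_vector <- function(segs, len, chrom = "chrT") {
  v <- logical(len)
  m <- segs$segments[[chrom]]
  if (!is.null(m) && nrow(m))
    for (i in seq_len(nrow(m))) v[(m[i, 1] + 1):m[i, 2]] <- TRUE
  v
}

oracle_bp_overlap <- function(a, b, len, chrom = "chrT") {
  sum(coverage_vector(a, len, chrom) & coverage_vector(b, len, chrom))
}

oracle_points_in_segments <- function(points, segs, chrom = "chrT") {
  p <- points$positions[[chrom]]
  m <- segs$segments[[chrom]]
  if (is.null(m) || !nrow(m)) return(0L)
  n <- 0L
  for (x in p)
    for (i in seq_len(nrow(m)))
      if (x >= m[i, 1] && x < m[i, 2]) { n <- n + 1L; break }
  n
}

# O(n^2) Kendall tau-b with tie correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_border_affinity <- function(points, segs, chrom = "chrT") {
  p <- points$positions[[chrom]]
  m <- segs$segments[[chrom]]
  d <- c()
  for (x in p) for (i in seq_len(nrow(m)))
    if (x >= m[i, 1] && x < m[i, 2])
      d <- c(d, min(x - m[i, 1], m[i, 2] - 1 - x) / (m[i, 2] - m[i, 1]))
  if (!length(d)) return(NA_real_)
  mean(d)
}

oracle_nearest_segment_distance <- function(points, segs, chrom = "chrT") {
  p <- points$positions[[chrom]]
  m <- segs$segments[[chrom]]
  if (!length(p) || is.null(m) || !nrow(m)) return(NA_real_)
  mean(sapply(p, function(x) {
    min(sapply(seq_len(nrow(m)), function(i) {
      if (x >= m[i, 1] && x < m[i, 2]) 0
      else if (x < m[i, 1]) m[i, 1] - x
      else x - (m[i, 2] - 1)
    }))
  }))
}

# step-up BH by its definition: largest k with p_(k) <= k q / m
oracle_bh_calls <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  calls <- logical(m)
  if (length(k)) calls[o[seq_len(max(k))]] <- TRUE
  calls
}

oracle_bh_adjusted <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

one_bin <- function(len, chrom = "chrT") {
  list(bin_id = "global", chrom = chrom, start = 0, end = len)
}
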