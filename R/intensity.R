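# The intensity algebra.  An intensity track is a nonnegative per-bp
# function lambda(b) governing where randomized points land; it is the
# vehicle for confounder-aware null models (randomize points so that they
# mimic a covariate such as GC content, rather than uniformly).

new_intensity <- function(values, normalization = "raw") {
  tr <- function_track(values)
  for (v in tr$values)
    if (any(v < 0, na.rm = TRUE)) stop("intensity values must be >= 0")
  structure(tr, class = c("IntensityTrack", class(tr)),
            normalization = normalization)
}

#' Constant intensity over a region
#'
#' `lambda(b) = c` on the region; randomizing points under it is
#' equivalent to uniform randomization.
#'
#' @param c positive constant.
#' @param region list with `chrom`, `start`, `end` (0-based half-open).
#' @return an `IntensityTrack`.
#' @export
constant_intensity <- function(c, region) {
  if (c <= 0) stop("c must be positive")
  v <- rep(NA_real_, region$end)
  v[(region$start + 1):region$end] <- c
  new_intensity(setNames(list(v), region$chrom))
}

#' Linear combination of covariate tracks
#'
#' `lambda(b) = max(0, c + sum_i beta_i g_i(b))`, defined where every
#' covariate is defined.  Negative values are clipped to zero; the number
#' of clipped bp is reported via a message.  For a guaranteed-positive
#' model use [fit_intensity()]'s log-linear form.
#'
#' @param c intercept.
#' @param betas numeric coefficients, one per covariate.
#' @param covariates list of `FunctionTrack`s, jointly defined.
#' @return an `IntensityTrack`.
#' @export
linear_combination <- function(c, betas, covariates) {
  if (length(betas) != length(covariates))
    stop("need one beta per covariate")
  if (!length(covariates)) {
    stop("no covariates; use constant_intensity() for a constant")
  }
  chroms <- Reduce(intersect, lapply(covariates, track_chroms))
  if (!length(chroms)) stop("covariates share no chromosome")
  out <- list()
  clipped <- 0L
  for (ch in chroms) {
    n <- min(vapply(covariates, function(f) length(f$values[[ch]]), 1L))
    acc <- rep(c, n)
    for (i in seq_along(covariates))
      acc <- acc + betas[i] * covariates[[i]]$values[[ch]][seq_len(n)]
    clipped <- clipped + sum(acc < 0, na.rm = TRUE)
    acc[acc < 0] <- 0
    out[[ch]] <- acc
  }
  if (clipped > 0L)
    message(clipped, " bp clipped at zero in linear intensity")
  new_intensity(out)
}

#' Kernel density intensity from observed points
#'
#' A Gaussian kernel density estimate of the observed point positions,
#' evaluated at every bp of the region and renormalized so the intensity
#' sums to the point count (which also compensates kernel mass lost over
#' the region edges).
#'
#' @param points a `PointTrack` with points on the region's chromosome.
#' @param bandwidth kernel standard deviation in bp.
#' @param region list with `chrom`, `start`, `end`.
#' @return an `IntensityTrack` with `sum(lambda) = point count`.
#' @export
kde_intensity <- function(points, bandwidth, region) {
  p <- points$positions[[region$chrom]]
  if (is.null(p) || !length(p)) stop("kde_intensity needs at least 1 point")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  len <- region$end - region$start
  d <- stats::density(p, bw = bandwidth, kernel = "gaussian",
                      from = region$start, to = region$end - 1, n = len)
  lam <- d$y
  lam[lam < 0] <- 0
  lam <- lam * length(p) / sum(lam)
  v <- rep(NA_real_, region$end)
  v[(region$start + 1):region$end] <- lam
  new_intensity(setNames(list(v), region$chrom), normalization = "sums-to-count")
}

#' Flanking-window GC content functions
#'
#' From a 0/1 per-bp GC indicator, builds the pair of functions `L` and
#' `R` assigning to each base the GC content of its `window`-bp left and
#' right flanks, weighted by a linearly decreasing function of the
#' distance: weight `w_i = 2 (w - i + 1) / (w (w + 1))` at distance
#' `i = 1..w`, so the weights sum to 1 and exclude the base itself.
#' Values are undefined within `window` bp of a chromosome end and
#' wherever a flank touches an undefined position.
#'
#' @param gc_indicator a `FunctionTrack` with values in `{0, 1}`.
#' @param window flank width in bp (default 100).
#' @return list with `L` and `R`, both `FunctionTrack`s.
#' @export
gc_flank_functions <- function(gc_indicator, window = 100L) {
  if (window < 1L) stop("window must be >= 1")
  vals <- gc_indicator$values
  for (v in vals)
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("gc_indicator must be 0/1 where defined")
  w <- as.integer(window)
  wts <- 2 * (w - seq_len(w) + 1) / (w * (w + 1))
  shift_sum <- function(v, dir) {
    n <- length(v)
    acc <- rep(0, n)
    for (i in seq_len(w)) {
      shifted <- rep(NA_real_, n)
      if (dir < 0) {
        if (i < n) shifted[(i + 1):n] <- v[1:(n - i)]
      } else {
        if (i < n) shifted[1:(n - i)] <- v[(i + 1):n]
      }
      acc <- acc + wts[i] * shifted  # NA propagates into acc
    }
    acc
  }
  list(L = function_track(lapply(vals, shift_sum, dir = -1L)),
       R = function_track(lapply(vals, shift_sum, dir = +1L)))
}

#' Fit an intensity to observed points given covariates
#'
#' Log-linear point-process regression: per-bp point presence is modelled
#' as Poisson with `log lambda(b) = c + sum_i beta_i g_i(b)` and fitted by
#' maximum likelihood over the defined bp of the region.  The log link
#' guarantees a positive intensity.  The fitted curve is returned
#' normalized to the observed point count, with the coefficient table in
#' attribute `fit` (estimates and standard errors).
#'
#' @param points a `PointTrack` (at least 10 points on the region).
#' @param covariates list of `FunctionTrack`s defined on the region.
#' @param region list with `chrom`, `start`, `end`.
#' @param genome a [genome_context()] (for the mask).
#' @return an `IntensityTrack`; attribute `fit` holds the glm coefficient
#'   matrix.
#' @export
fit_intensity <- function(points, covariates, region, genome) {
  ch <- region$chrom
  pos <- defined_positions(genome, ch, region$start, region$end)
  p <- points$positions[[ch]]
  if (is.null(p) || sum(p >= region$start & p < region$end) < 10L)
    stop("fit_intensity needs at least 10 points on the region")
  y <- as.integer(pos %in% p)
  if (length(covariates)) {
    X <- vapply(covariates, function(f) {
      v <- f$values[[ch]]
      out <- rep(NA_real_, length(pos))
      ok <- pos < length(v)
      out[ok] <- v[pos[ok] + 1]
      out
    }, numeric(length(pos)))
    X <- matrix(X, nrow = length(pos))
    keep <- stats::complete.cases(X)
    if (sum(keep) < 10L)
      stop("covariates undefined on almost all of the region")
    dat <- data.frame(y = y[keep], X[keep, , drop = FALSE])
    names(dat)[-1L] <- paste0("g", seq_along(covariates))
  } else {
    keep <- rep(TRUE, length(pos))
    dat <- data.frame(y = y)
  }
  fo <- if (ncol(dat) == 1L) y ~ 1 else y ~ .
  fit <- stats::glm(fo, data = dat, family = stats::poisson())
  if (!fit$converged)
    stop("intensity fit did not converge (deviance ", format(fit$deviance),
         ")")
  lam_def <- as.numeric(stats::predict(fit, type = "response"))
  v <- rep(NA_real_, region$end)
  v[pos[keep] + 1] <- lam_def
  out <- new_intensity(setNames(list(v), ch), normalization = "sums-to-count")
  out <- normalize_intensity(out, sum(y))
  attr(out, "fit") <- summary(fit)$coefficients
  out
}

#' Rescale an intensity to a target total
#'
#' Scales the intensity so that its defined values sum to `n`.  Point
#' randomization is invariant to positive rescaling; normalization mainly
#' aids comparison and simulation.
#'
#' @param intensity an `IntensityTrack`.
#' @param n target total (e.g. an observed point count).
#' @return rescaled `IntensityTrack`.
#' @export
normalize_intensity <- function(intensity, n) {
  tot <- sum(vapply(intensity$values, function(v) sum(v, na.rm = TRUE),
                    numeric(1)))
  if (tot <= 0) stop("cannot normalize an all-zero intensity")
  fit <- attr(intensity, "fit")
  intensity$values <- lapply(intensity$values, function(v) v * n / tot)
  out <- new_intensity(intensity$values, normalization = "sums-to-count")
  attr(out, "fit") <- fit
  out
}
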