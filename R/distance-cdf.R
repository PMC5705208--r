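#' Piecewise-linear cumulative distance distribution
#'
#' The currency of the random-placement null model: a cumulative
#' distribution of distance-to-nearest-soma (um), linear between
#' breakpoints. Probabilities must be non-decreasing, start at 0 and end at
#' 1; breakpoints must be strictly increasing.
#'
#' @param breakpoints sorted distances (um).
#' @param cum_probs cumulative probabilities at the breakpoints.
#' @return an object of class `distance_cdf`.
#' @export
distance_cdf <- function(breakpoints, cum_probs) {
  if (length(breakpoints) != length(cum_probs) || length(breakpoints) < 2) {
    stopf("need matching breakpoint and probability vectors (length >= 2)")
  }
  o <- order(breakpoints)
  breakpoints <- as.numeric(breakpoints[o])
  cum_probs <- as.numeric(cum_probs[o])
  keep <- c(TRUE, diff(breakpoints) > 1e-12)
  breakpoints <- breakpoints[keep]
  cum_probs <- cum_probs[keep]
  if (any(diff(cum_probs) < -1e-9)) stopf("cumulative probabilities decrease")
  cum_probs <- cummax(pmin(pmax(cum_probs, 0), 1))
  if (abs(cum_probs[1]) > 1e-9) {
    stopf("cumulative probability must start at 0")
  }
  if (abs(cum_probs[length(cum_probs)] - 1) > 1e-9) {
    stopf("cumulative probability must end at 1")
  }
  cum_probs[1] <- 0
  cum_probs[length(cum_probs)] <- 1
  structure(list(breakpoints = breakpoints, cum_probs = cum_probs),
            class = "distance_cdf")
}

#' Evaluate a piecewise-linear CDF
#'
#' @param cdf a [distance_cdf()].
#' @param q distances (um).
#' @return cumulative probabilities at `q` (0 below support, 1 above).
#' @export
cdf_prob <- function(cdf, q) {
  stopifnot(inherits(cdf, "distance_cdf"))
  stats::approx(cdf$breakpoints, cdf$cum_probs, xout = q,
                yleft = 0, yright = 1, ties = "ordered")$y
}

#' Quantiles of a piecewise-linear CDF
#'
#' Inverse linear interpolation; within a flat stretch of the CDF the
#' left-most attaining distance is returned.
#'
#' @param x a [distance_cdf()].
#' @param probs probabilities in \[0, 1\].
#' @param ... unused.
#' @return distances in um.
#' @export
quantile.distance_cdf <- function(x, probs = seq(0, 1, 0.25), ...) {
  stopifnot(all(probs >= 0 & probs <= 1))
  vapply(probs, function(p) {
    i <- which(x$cum_probs >= p - 1e-12)[1]
    if (i == 1) return(x$breakpoints[1])
    p0 <- x$cum_probs[i - 1]; p1 <- x$cum_probs[i]
    b0 <- x$breakpoints[i - 1]; b1 <- x$breakpoints[i]
    if (p1 - p0 < 1e-15) return(b1)
    b0 + (p - p0) / (p1 - p0) * (b1 - b0)
  }, 0)
}

#' @export
print.distance_cdf <- function(x, ...) {
  cat(sprintf(
    "<distance_cdf> support [%.3g, %.3g] um, %d breakpoints, median %.3g um\n",
    x$breakpoints[1], x$breakpoints[length(x$breakpoints)],
    length(x$breakpoints), quantile(x, 0.5)))
  invisible(x)
}

#' @export
plot.distance_cdf <- function(x, ...,
                              xlab = "distance to nearest soma (µm)",
                              ylab = "cumulative probability", type = "l") {
  graphics::plot(x$breakpoints, x$cum_probs, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Average several distance CDFs
#'
#' Pointwise (weighted) mean of piecewise-linear CDFs, evaluated at the
#' union of their breakpoints; the result is again piecewise linear. The
#' default gives every image equal weight; `weights` (e.g. capillary
#' lengths) enables a length-weighted sensitivity variant.
#'
#' @param cdfs list of [distance_cdf()] objects.
#' @param weights optional non-negative weights, one per CDF.
#' @return a [distance_cdf()].
#' @export
pool_cdfs <- function(cdfs, weights = NULL) {
  if (length(cdfs) == 0) stopf("no images: need at least one CDF to pool")
  stopifnot(all(vapply(cdfs, inherits, TRUE, "distance_cdf")))
  if (is.null(weights)) weights <- rep(1, length(cdfs))
  if (length(weights) != length(cdfs) || any(weights < 0) ||
      sum(weights) <= 0) {
    stopf("weights must be non-negative with positive sum")
  }
  weights <- weights / sum(weights)
  bp <- sort(unique(unlist(lapply(cdfs, `[[`, "breakpoints"))))
  vals <- vapply(seq_along(cdfs),
                 function(i) weights[i] * cdf_prob(cdfs[[i]], bp),
                 numeric(length(bp)))
  p <- if (is.matrix(vals)) rowSums(vals) else sum(vals)
  distance_cdf(bp, p)
}

#' Equi-probability sample from a distance CDF
#'
#' Represents a continuous CDF by `n` quantiles at evenly spaced cumulative
#' probabilities, mirroring how a smooth predicted distribution is reduced
#' to the same resolution as `n` experimental observations. The default
#' midpoint convention uses probabilities (i - 1/2)/n; `convention = "right"`
#' uses i/n.
#'
#' @param cdf a [distance_cdf()].
#' @param n number of sample points (>= 1).
#' @param convention `"midpoint"` (default) or `"right"`.
#' @return sorted distances in um.
#' @export
equiprobability_sample <- function(cdf, n,
                                   convention = c("midpoint", "right")) {
  convention <- match.arg(convention)
  if (!is_count(n) || n < 1) stopf("invalid n: need a positive integer")
  p <- if (convention == "midpoint") (seq_len(n) - 0.5) / n
       else seq_len(n) / n
  sort(quantile(cdf, p))
}

#' Idealized linear null distribution
#'
#' For uniformly spaced somata on an unbranched, untruncated capillary the
#' random-placement distance CDF rises linearly to 1 at half the inter-soma
#' spacing.
#'
#' @param half_spacing um; half the inter-soma spacing (30 um for the
#'   default 60 um spacing).
#' @return a [distance_cdf()].
#' @export
linear_null <- function(half_spacing) {
  if (!is.numeric(half_spacing) || length(half_spacing) != 1 ||
      !is.finite(half_spacing) || half_spacing <= 0) {
    stopf("invalid spacing: half_spacing must be positive")
  }
  distance_cdf(c(0, half_spacing), c(0, 1))
}

#' Write / read a distance CDF as two-column CSV
#'
#' @param cdf a [distance_cdf()].
#' @param path CSV path with columns `distance_um`, `cum_prob`.
#' @return `path` invisibly / a [distance_cdf()].
#' @export
write_distance_cdf <- function(cdf, path) {
  utils::write.csv(
    data.frame(distance_um = cdf$breakpoints, cum_prob = cdf$cum_probs),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_cdf
#' @export
read_distance_cdf <- function(path) {
  df <- utils::read.csv(path)
  distance_cdf(df$distance_um, df$cum_prob)
}
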