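# Observed blockage-to-soma distances and their comparison with the
# random-placement null.

#' Observed blockage-to-nearest-soma distances across images
#'
#' One distance per annotated blockage, measured along the vessel to the
#' nearest visible pericyte soma. Blockages with no reachable visible soma
#' are excluded with a warning.
#'
#' @param graphs list of [capillary_graph()] objects.
#' @param restrict soma search restriction, as in [nearest_soma_distance()].
#' @return list with `distances` (um, in encounter order), `ecdf`
#'   (a [stats::ecdf()]) and `median` (um, mid-rank convention).
#' @export
observed_distances <- function(graphs, restrict = c("capillary", "component")) {
  restrict <- match.arg(restrict)
  if (inherits(graphs, "capillary_graph")) graphs <- list(graphs)
  d <- numeric()
  dropped <- 0L
  for (g in graphs) {
    if (nrow(g$blockages) == 0) next
    for (i in seq_len(nrow(g$blockages))) {
      res <- tryCatch(
        nearest_soma_distance(g, point_on_vessel(g$blockages$segment[i],
                                                 g$blockages$arc_pos[i]),
                              restrict),
        error = function(e) NULL)
      if (is.null(res)) dropped <- dropped + 1L else d <- c(d, res$distance)
    }
  }
  if (dropped > 0) {
    warnf("%d blockage(s) had no reachable visible soma and were excluded",
          dropped)
  }
  if (length(d) == 0) stopf("no measurable blockages in the image set")
  list(distances = d, ecdf = stats::ecdf(d), median = midrank_median(d))
}

#' Compare observed blockage distances with a null distribution
#'
#' Primary comparison: one-sample Kolmogorov-Smirnov test of the observed
#' distances against the continuous null CDF. For parity with comparing two
#' n-point distributions, a two-sample KS test against an equi-probability
#' sample of the null (size `n_sample`) is co-reported. Both p-values are
#' two-sided.
#'
#' @param observed numeric vector of observed distances (um).
#' @param null a [distance_cdf()].
#' @param n_sample size of the equi-probability sample (default: number of
#'   observations). Values below 2 skip the two-sample variant with a
#'   warning.
#' @return list with `KS_D`, `p_one_sample`, `p_two_sample`,
#'   `observed_median`, `predicted_median`.
#' @export
compare_to_null <- function(observed, null, n_sample = length(observed)) {
  if (length(observed) == 0) stopf("no observed distances")
  stopifnot(inherits(null, "distance_cdf"))
  one <- suppressWarnings(
    stats::ks.test(observed, function(q) cdf_prob(null, q)))
  p_two <- NA_real_
  if (n_sample < 2) {
    warnf("n_sample < 2: two-sample comparison skipped")
  } else {
    two <- suppressWarnings(
      stats::ks.test(observed, equiprobability_sample(null, n_sample)))
    p_two <- two$p.value
  }
  list(KS_D = unname(one$statistic), p_one_sample = one$p.value,
       p_two_sample = p_two,
       observed_median = midrank_median(observed),
       predicted_median = unname(quantile(null, 0.5)))
}

#' Pericyte-blockage association analysis of an image set
#'
#' The central estimator of the package: given a set of annotated capillary
#' graphs, measures every blockage's along-vessel distance to the nearest
#' visible pericyte soma, fits the exact random-placement null model on the
#' same blocked capillaries, and tests whether blockages sit closer to
#' pericyte somata than random placement predicts. An idealized linear null
#' (rising to 1 at half the configured inter-soma spacing) is compared
#' alongside.
#'
#' @param graphs list of [capillary_graph()] objects.
#' @param intersoma_spacing um; spacing used for the idealized linear null
#'   (default 60).
#' @param n_sample equi-probability sample size (default: number of
#'   observed blockages).
#' @param weighting,restrict passed to [null_model()].
#' @return an object of class `pericyte_association` with `observed`,
#'   `null`, `comparison`, `linear_comparison` and `n` components.
#' @examples
#' cfg <- study_config()
#' graphs <- lapply(1:6, function(i) {
#'   g <- generate_bed(cfg, seed = i)
#'   assign_condition(g, "ischaemia", cfg, seed = i)$graph
#' })
#' fit <- pericyte_association(graphs)
#' print(fit)
#' @export
pericyte_association <- function(graphs, intersoma_spacing = 60,
                                 n_sample = NULL,
                                 weighting = c("image", "length"),
                                 restrict = c("capillary", "component")) {
  weighting <- match.arg(weighting)
  restrict <- match.arg(restrict)
  obs <- observed_distances(graphs, restrict)
  if (is.null(n_sample)) n_sample <- length(obs$distances)
  nm <- null_model(graphs, n_sample = n_sample, weighting = weighting,
                   restrict = restrict)
  cmp <- compare_to_null(obs$distances, nm$pooled, n_sample)
  lin <- linear_null(intersoma_spacing / 2)
  lin_cmp <- compare_to_null(obs$distances, lin, n_sample)
  structure(list(observed = obs, null = nm, comparison = cmp,
                 linear_comparison = lin_cmp,
                 intersoma_spacing = intersoma_spacing,
                 n = length(obs$distances)),
            class = "pericyte_association")
}

#' @export
print.pericyte_association <- function(x, ...) {
  cat("Pericyte-blockage association analysis\n")
  cat(sprintf("  blockages measured:        %d\n", x$n))
  cat(sprintf("  observed median distance:  %.2f um\n",
              x$comparison$observed_median))
  cat(sprintf("  null (random) median:      %.2f um\n",
              x$comparison$predicted_median))
  cat(sprintf("  KS vs exact null:          D = %.3f, p = %.3g (one-sample), p = %.3g (two-sample)\n",
              x$comparison$KS_D, x$comparison$p_one_sample,
              x$comparison$p_two_sample))
  cat(sprintf("  KS vs linear null (%g um): p = %.3g\n",
              x$intersoma_spacing / 2, x$linear_comparison$p_one_sample))
  invisible(x)
}

#' @export
summary.pericyte_association <- function(object, ...) {
  out <- list(
    n = object$n,
    observed_median = object$comparison$observed_median,
    predicted_median = object$comparison$predicted_median,
    KS_D = object$comparison$KS_D,
    p_one_sample = object$comparison$p_one_sample,
    p_two_sample = object$comparison$p_two_sample,
    p_linear_null = object$linear_comparison$p_one_sample)
  class(out) <- "summary.pericyte_association"
  out
}

#' @export
print.summary.pericyte_association <- function(x, ...) {
  cat(sprintf(
    "n = %d blockages; median %.2f um observed vs %.2f um predicted; KS D = %.3f (p = %.3g)\n",
    x$n, x$observed_median, x$predicted_median, x$KS_D, x$p_one_sample))
  invisible(x)
}

#' @export
plot.pericyte_association <- function(x, ...) {
  obs <- sort(x$observed$distances)
  graphics::plot(x$null$pooled, col = "grey40", lty = 2,
                 xlim = range(c(obs, x$null$pooled$breakpoints)),
                 main = "Blockage distance to nearest pericyte soma", ...)
  graphics::lines(stats::stepfun(obs, seq(0, 1, length.out = length(obs) + 1)),
                  do.points = FALSE, col = "black")
  lin <- linear_null(x$intersoma_spacing / 2)
  graphics::lines(lin$breakpoints, lin$cum_probs, col = "steelblue", lty = 3)
  graphics::legend("bottomright", legend = c("observed", "exact null",
                                             "linear null"),
                   col = c("black", "grey40", "steelblue"), lty = c(1, 2, 3),
                   bty = "n")
  invisible(x)
}
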