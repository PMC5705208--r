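# Exact random-placement null model for blockage-to-nearest-soma distance.

#' Exact per-image null CDF for random blockage placement
#'
#' Distribution of the distance to the nearest visible pericyte soma for a
#' blockage placed uniformly at random along the imaged arc length of one
#' capillary. For a capillary of imaged length L with a single soma a
#' distance A from one end this reduces to the density 2/L for x < A, 1/L
#' for A < x < L - A and 0 beyond; branching capillaries and capillaries
#' truncated by the image edge are handled by the same construction: the
#' capillary is partitioned into elementary intervals (at somata, branch
#' nodes, segment/image ends and equidistance points between competing
#' somata) on which the nearest-soma distance is affine with slope +-1, and
#' each interval of length l contributes probability mass l/L uniformly
#' over its distance range.
#'
#' @param graph a [capillary_graph()].
#' @param blocked_capillary_id name of the blocked capillary.
#' @param restrict soma search restriction, as in
#'   [nearest_soma_distance()].
#' @return a [distance_cdf()].
#' @export
image_null_cdf <- function(graph, blocked_capillary_id,
                           restrict = c("capillary", "component")) {
  restrict <- match.arg(restrict)
  L <- capillary_length(graph, blocked_capillary_id)
  if (L <= 0) stopf("degenerate geometry: capillary has zero imaged length")
  env <- distance_envelope(graph, blocked_capillary_id, restrict)
  lo <- hi <- mass <- numeric()
  for (e in env) {
    ns <- length(e$s)
    if (ns < 2) next
    s1 <- e$s[-ns]; s2 <- e$s[-1]
    d1 <- e$d[-ns]; d2 <- e$d[-1]
    keep <- (s2 - s1) > 1e-12
    lo <- c(lo, pmin(d1, d2)[keep])
    hi <- c(hi, pmax(d1, d2)[keep])
    mass <- c(mass, (s2 - s1)[keep] / L)
  }
  if (!any(is.finite(lo))) stopf("degenerate geometry: no reachable soma")
  knots <- sort(unique(c(0, lo, hi)))
  dens <- numeric(length(knots) - 1)
  for (i in seq_along(mass)) {
    cover <- knots[-length(knots)] >= lo[i] - 1e-12 &
      knots[-1] <= hi[i] + 1e-12
    dens[cover] <- dens[cover] + mass[i] / (hi[i] - lo[i])
  }
  cum <- c(0, cumsum(dens * diff(knots)))
  distance_cdf(knots, cum / cum[length(cum)])
}

#' Fit the pooled random-placement null model over a set of images
#'
#' Computes the exact null CDF for every blocked capillary, averages within
#' each image, pools across images (equal weight per image by default) and
#' reduces the pooled CDF to `n_sample` equi-probability points. Capillaries
#' are taken to be blocked if they carry a blockage annotation, unless
#' `blocked_ids` names them explicitly.
#'
#' @param graphs list of [capillary_graph()] objects (one per image).
#' @param blocked_ids optional list (parallel to `graphs`) of character
#'   vectors naming the blocked capillaries in each image.
#' @param n_sample number of equi-probability sampling points (default: the
#'   number of images).
#' @param weighting `"image"` (equal weight per image, default) or
#'   `"length"` (weight by blocked-capillary arc length).
#' @param restrict soma search restriction, as in [nearest_soma_distance()].
#' @return an object of class `null_model`: list with `per_image_cdfs`,
#'   `pooled` ([distance_cdf()]), `samples` (equi-probability sample) and
#'   `predicted_median` (um).
#' @export
null_model <- function(graphs, blocked_ids = NULL, n_sample = length(graphs),
                       weighting = c("image", "length"),
                       restrict = c("capillary", "component")) {
  weighting <- match.arg(weighting)
  restrict <- match.arg(restrict)
  if (length(graphs) == 0) stopf("no images: need at least one graph")
  per_image <- list()
  img_weight <- numeric()
  dropped <- 0L
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    ids <- if (!is.null(blocked_ids)) blocked_ids[[i]] else
      unique(g$capillary_ids[g$blockages$segment])
    # a blocked capillary with no visible soma yields no measurable
    # distance; it is excluded here exactly as in observed_distances()
    measurable <- vapply(ids, function(id) {
      length(soma_candidates(g, if (restrict == "capillary") id)) > 0
    }, TRUE)
    dropped <- dropped + sum(!measurable)
    ids <- ids[measurable]
    if (length(ids) == 0) next
    cdfs <- lapply(ids, function(id) image_null_cdf(g, id, restrict))
    lens <- vapply(ids, function(id) capillary_length(g, id), 0)
    w <- if (weighting == "length") lens else rep(1, length(cdfs))
    per_image[[length(per_image) + 1]] <- pool_cdfs(cdfs, w)
    img_weight <- c(img_weight, if (weighting == "length") sum(lens) else 1)
  }
  if (dropped > 0) {
    warnf("%d blocked capillar(ies) without a visible soma excluded from the null",
          dropped)
  }
  if (length(per_image) == 0) stopf("no blocked capillaries in any image")
  pooled <- pool_cdfs(per_image, img_weight)
  samples <- equiprobability_sample(pooled, n_sample)
  structure(list(per_image_cdfs = per_image, pooled = pooled,
                 samples = samples,
                 predicted_median = unname(quantile(pooled, 0.5))),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "<null_model> pooled over %d images; predicted median %.2f um; %d equi-probability samples\n",
    length(x$per_image_cdfs), x$predicted_median, length(x$samples)))
  invisible(x)
}

#' Write a null-model result as a JSON report plus per-image CSVs
#'
#' @param x a [null_model()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_null_model <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_along(x$per_image_cdfs)) {
    f <- sprintf("null_cdf_image%03d.csv", i)
    write_distance_cdf(x$per_image_cdfs[[i]], file.path(dir, f))
    files <- c(files, f)
  }
  write_distance_cdf(x$pooled, file.path(dir, "null_cdf_pooled.csv"))
  jsonlite::write_json(
    list(per_image_csvs = files, pooled_csv = "null_cdf_pooled.csv",
         samples = x$samples, predicted_median = x$predicted_median),
    file.path(dir, "null_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
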