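# Lumen intensity profiles and blockage detection.

#' Lumen intensity profile along a capillary centerline
#'
#' @param arc_positions um, uniformly spaced and strictly increasing.
#' @param intensities fluorescence (a.u.); negative values after background
#'   subtraction are clamped to zero downstream.
#' @param background scalar background offset to subtract before analysis.
#' @return an object of class `lumen_profile`.
#' @export
lumen_profile <- function(arc_positions, intensities, background = 0) {
  arc_positions <- as.numeric(arc_positions)
  intensities <- as.numeric(intensities)
  if (length(arc_positions) != length(intensities) ||
      length(arc_positions) < 10) {
    stopf("profile needs >= 10 matched samples")
  }
  st <- diff(arc_positions)
  if (any(st <= 0) || max(st) - min(st) > 1e-6 * mean(st)) {
    stopf("arc positions must increase with a constant step")
  }
  structure(list(arc_positions = arc_positions, intensities = intensities,
                 background = as.numeric(background)),
            class = "lumen_profile")
}

#' @export
print.lumen_profile <- function(x, ...) {
  cat(sprintf("<lumen_profile> %d samples over %.1f um (step %.3g um)\n",
              length(x$arc_positions),
              diff(range(x$arc_positions)), x$arc_positions[2] -
                x$arc_positions[1]))
  invisible(x)
}

profile_normalized <- function(profile) {
  v <- pmax(profile$intensities - profile$background, 0)
  n_up <- max(1L, floor(length(v) * 0.25))
  plateau <- stats::median(v[seq_len(n_up)])
  list(values = v, plateau = plateau,
       norm = if (plateau > 0) v / plateau else v * 0)
}

#' Detect an abrupt perfusion block in a lumen profile
#'
#' After background subtraction and normalization to the upstream plateau
#' (median of the first 25% of samples), a block is called at the first
#' downward crossing of `cross` for which the intensity falls from >= `hi`
#' to <= `lo` within a window of at most `max_width` um. The reported
#' position is the crossing point by linear interpolation. The thresholds
#' operationalize "abrupt termination" and are deliberately exposed.
#'
#' @param profile a [lumen_profile()].
#' @param hi,lo,cross normalized intensity thresholds (defaults 0.8, 0.2,
#'   0.5).
#' @param max_width maximum um allowed for the `hi` to `lo` fall (default
#'   5).
#' @return a `block_call` list (`position`, `upstream_level`,
#'   `downstream_level`, `width`) or `NULL` if no block is found. When
#'   several candidate drops exist the most upstream one is returned with a
#'   warning.
#' @export
detect_block <- function(profile, hi = 0.8, lo = 0.2, cross = 0.5,
                         max_width = 5) {
  stopifnot(inherits(profile, "lumen_profile"))
  nz <- profile_normalized(profile)
  if (nz$plateau <= 0) return(NULL)
  s <- profile$arc_positions
  y <- nz$norm
  n <- length(y)
  crossings <- which(y[-n] >= cross & y[-1] < cross)
  calls <- list()
  seen_hi <- numeric()  # crossings sharing an upstream shoulder are one drop
  for (k in crossings) {
    before <- which(y[seq_len(k)] >= hi)
    after <- which(y[(k + 1):n] <= lo)
    if (length(before) == 0 || length(after) == 0) next
    t_hi <- s[max(before)]
    t_lo <- s[k + min(after)]
    if (t_lo - t_hi > max_width) next
    if (t_hi %in% seen_hi) next
    seen_hi <- c(seen_hi, t_hi)
    pos <- s[k] + (cross - y[k]) / (y[k + 1] - y[k]) * (s[k + 1] - s[k])
    down <- nz$values[s >= t_lo]
    calls[[length(calls) + 1]] <- structure(
      list(position = pos, upstream_level = nz$plateau,
           downstream_level = stats::median(down), width = t_lo - t_hi),
      class = "block_call")
  }
  if (length(calls) == 0) return(NULL)
  if (length(calls) > 1) {
    warnf("%d candidate drops; returning the most upstream", length(calls))
  }
  calls[[1]]
}

#' Average aligned lumen profiles across block sites
#'
#' Profiles are background-subtracted, normalized to their upstream
#' plateaus, shifted so the block call sits at offset 0, resampled onto a
#' common grid and averaged pointwise with per-point s.e.m.
#'
#' @param profiles list of [lumen_profile()] objects.
#' @param calls matching list of block calls (from [detect_block()]);
#'   computed if `NULL`.
#' @param step grid step in um (default: the first profile's step).
#' @return list with `offset` (um relative to the block), `mean`, `sem`
#'   (NA where fewer than 2 profiles contribute) and `n` per grid point.
#' @export
aggregate_profiles <- function(profiles, calls = NULL, step = NULL) {
  if (length(profiles) == 0) stopf("no profiles to aggregate")
  if (is.null(calls)) calls <- lapply(profiles, detect_block)
  if (any(vapply(calls, is.null, TRUE))) {
    stopf("every profile must have a block call")
  }
  if (is.null(step)) {
    step <- diff(profiles[[1]]$arc_positions[1:2])
  }
  shifted <- Map(function(p, cl) {
    list(s = p$arc_positions - cl$position, y = profile_normalized(p)$norm)
  }, profiles, calls)
  lo <- min(vapply(shifted, function(z) min(z$s), 0))
  hi <- max(vapply(shifted, function(z) max(z$s), 0))
  grid <- seq(lo, hi, by = step)
  mat <- vapply(shifted, function(z) {
    stats::approx(z$s, z$y, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  n <- rowSums(!is.na(mat))
  m <- rowMeans(mat, na.rm = TRUE)
  s <- apply(mat, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) NA_real_ else stats::sd(r) / sqrt(length(r))
  })
  m[n == 0] <- NA_real_
  list(offset = grid, mean = m, sem = s, n = n)
}

#' Write / read a lumen profile as CSV
#'
#' @param profile a [lumen_profile()].
#' @param path CSV path with columns `arc_um`, `intensity` (background is
#'   stored as an attribute column `background` repeated per row).
#' @return `path` invisibly / a [lumen_profile()].
#' @export
write_lumen_profile <- function(profile, path) {
  utils::write.csv(
    data.frame(arc_um = profile$arc_positions,
               intensity = profile$intensities,
               background = profile$background),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lumen_profile
#' @export
read_lumen_profile <- function(path) {
  df <- utils::read.csv(path)
  lumen_profile(df$arc_um, df$intensity, background = df$background[1] %||% 0)
}
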