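# Geodesic (along-vessel) distance computations on capillary graphs.
#
# All distances are arc lengths in micrometres. A path between two on-vessel
# points either stays on one segment or leaves through a segment endpoint;
# endpoint-to-endpoint distances come from the precomputed node matrix.

#' Along-vessel distance between two points on a capillary graph
#'
#' Shortest path length measured along the vessel network (a geodesic on the
#' metric graph), never through free space.
#'
#' @param graph a [capillary_graph()].
#' @param a,b points created with [point_on_vessel()] (or `c(segment, arc)`).
#' @return distance in um.
#' @export
arc_distance <- function(graph, a, b) {
  a <- check_point(graph, a)
  b <- check_point(graph, b)
  d <- point_point_distance(graph, a$segment, a$arc_pos, b$segment, b$arc_pos)
  if (!is.finite(d)) stopf("points lie on disconnected components: unreachable")
  d
}

point_point_distance <- function(g, seg_a, arc_a, seg_b, arc_b) {
  best <- if (seg_a == seg_b) abs(arc_a - arc_b) else Inf
  na <- g$seg_nodes[seg_a, ]
  nb <- g$seg_nodes[seg_b, ]
  offs_a <- c(arc_a, g$seg_len[seg_a] - arc_a)
  offs_b <- c(arc_b, g$seg_len[seg_b] - arc_b)
  for (i in 1:2) for (j in 1:2) {
    best <- min(best, offs_a[i] + g$node_dist[na[i], nb[j]] + offs_b[j])
  }
  best
}

# distance from every node to a point on a segment
node_point_distance <- function(g, seg, arc) {
  nd <- g$node_dist
  pmin(nd[, g$seg_nodes[seg, 1]] + arc,
       nd[, g$seg_nodes[seg, 2]] + g$seg_len[seg] - arc)
}

soma_candidates <- function(g, capillary_id = NULL) {
  s <- g$somata
  keep <- s$visible
  if (!is.null(capillary_id)) {
    keep <- keep & g$capillary_ids[s$segment] == capillary_id
  }
  which(keep)
}

#' Distance from a point to the nearest visible pericyte soma
#'
#' Searches visible somata only (somata flagged `visible = FALSE`, e.g.
#' outside the imaged field, never compete). By default the search is
#' restricted to somata on the same named capillary as the query point,
#' matching the convention of measuring to the nearest visible soma on the
#' same capillary; `restrict = "component"` searches the whole connected
#' component instead.
#'
#' @param graph a [capillary_graph()].
#' @param p a [point_on_vessel()].
#' @param restrict `"capillary"` (default) or `"component"`.
#' @return list with `distance` (um) and `soma` (row index into
#'   `graph$somata`; ties broken by lowest index).
#' @export
nearest_soma_distance <- function(graph, p,
                                  restrict = c("capillary", "component")) {
  restrict <- match.arg(restrict)
  p <- check_point(graph, p)
  cap <- if (restrict == "capillary") graph$capillary_ids[p$segment] else NULL
  cand <- soma_candidates(graph, cap)
  if (length(cand) == 0) stopf("no visible soma to measure to: no soma")
  d <- vapply(cand, function(i) {
    point_point_distance(graph, p$segment, p$arc_pos,
                         graph$somata$segment[i], graph$somata$arc_pos[i])
  }, 0)
  if (!any(is.finite(d))) stopf("no reachable visible soma: no soma")
  k <- which.min(d)
  list(distance = d[k], soma = cand[k])
}

#' Along-vessel distances between adjacent pericyte somata
#'
#' For every capillary carrying at least two somata, returns the geodesic
#' distance between each pair of somata that are adjacent along the vessel
#' (no third soma lies on the path between them). With
#' `method = "euclidean"` the straight-line chord between soma positions is
#' returned instead, for comparison with measurements made in the imaging
#' plane.
#'
#' @param graph a [capillary_graph()].
#' @param method `"geodesic"` (default) or `"euclidean"`.
#' @return numeric vector of distances in um (empty if < 2 somata anywhere).
#' @export
intersoma_distances <- function(graph, method = c("geodesic", "euclidean")) {
  method <- match.arg(method)
  out <- numeric()
  for (cap in unique(graph$capillary_ids)) {
    idx <- soma_candidates(graph, cap)
    if (length(idx) < 2) next
    k <- length(idx)
    dm <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dm[i, j] <- dm[j, i] <- point_point_distance(
        graph,
        graph$somata$segment[idx[i]], graph$somata$arc_pos[idx[i]],
        graph$somata$segment[idx[j]], graph$somata$arc_pos[idx[j]])
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (!is.finite(dm[i, j])) next
      between <- FALSE
      for (m in seq_len(k)) {
        if (m == i || m == j) next
        if (dm[i, m] < dm[i, j] - 1e-9 && dm[m, j] < dm[i, j] - 1e-9 &&
            abs(dm[i, m] + dm[m, j] - dm[i, j]) < 1e-6) {
          between <- TRUE
          break
        }
      }
      if (!between) {
        if (method == "geodesic") {
          out <- c(out, dm[i, j])
        } else {
          out <- c(out, sqrt(sum((soma_coords(graph, idx[i]) -
                                    soma_coords(graph, idx[j]))^2)))
        }
      }
    }
  }
  out
}

soma_coords <- function(g, i) {
  point_coords(g, g$somata$segment[i], g$somata$arc_pos[i])
}

# Cartesian coordinates of an arc position on a segment polyline.
point_coords <- function(g, seg, arc) {
  m <- g$segments[[seg]]
  d <- sqrt(rowSums(diff(m)^2))
  cum <- c(0, cumsum(d))
  arc <- min(max(arc, 0), cum[length(cum)])
  i <- max(which(cum <= arc + 1e-12))
  if (i >= nrow(m)) return(m[nrow(m), ])
  f <- (arc - cum[i]) / d[i]
  m[i, ] + f * (m[i + 1, ] - m[i, ])
}

# Exact piecewise-linear profile of nearest-visible-soma distance along each
# segment of one capillary. On any subinterval free of on-segment somata the
# distance to each candidate soma is affine in the arc coordinate with slope
# +1 (routes through the segment start) or -1 (routes through the end), so
# the lower envelope is min(cplus + s, cminus - s) with at most one kink.
distance_envelope <- function(g, capillary_id,
                              restrict = c("capillary", "component")) {
  restrict <- match.arg(restrict)
  segs <- which(g$capillary_ids == capillary_id)
  if (length(segs) == 0) stopf("no capillary named '%s'", capillary_id)
  cand <- soma_candidates(g, if (restrict == "capillary") capillary_id)
  if (length(cand) == 0) {
    stopf("capillary '%s' has no visible soma: degenerate geometry",
          capillary_id)
  }
  lapply(segs, function(e) {
    len <- g$seg_len[e]
    d_start <- vapply(cand, function(i) {
      min(node_point_distance(g, g$somata$segment[i],
                              g$somata$arc_pos[i])[g$seg_nodes[e, 1]])
    }, 0)
    d_end <- vapply(cand, function(i) {
      min(node_point_distance(g, g$somata$segment[i],
                              g$somata$arc_pos[i])[g$seg_nodes[e, 2]])
    }, 0)
    on_seg <- g$somata$arc_pos[cand][g$somata$segment[cand] == e]
    cuts <- sort(unique(c(0, on_seg, len)))
    s_out <- 0
    d_out <- min(c(d_start, if (length(on_seg)) abs(on_seg)))
    for (k in seq_len(length(cuts) - 1)) {
      u <- cuts[k]; v <- cuts[k + 1]
      if (v - u <= 1e-12) next
      cplus <- suppressWarnings(min(c(d_start, -on_seg[on_seg <= u + 1e-12])))
      cminus <- suppressWarnings(min(c(d_end + len,
                                       on_seg[on_seg >= v - 1e-12])))
      pts <- v
      kink <- (cminus - cplus) / 2
      if (kink > u + 1e-12 && kink < v - 1e-12) pts <- c(kink, v)
      for (s in pts) {
        s_out <- c(s_out, s)
        d_out <- c(d_out, min(cplus + s, cminus - s))
      }
    }
    list(segment = e, s = s_out, d = d_out, length = len)
  })
}

#' Draw points uniformly over a capillary's imaged arc length
#'
#' @param graph a [capillary_graph()].
#' @param capillary_id capillary name.
#' @param n number of points.
#' @return data frame with columns `segment` and `arc_pos`.
#' @export
sample_uniform_on_capillary <- function(graph, capillary_id, n) {
  segs <- which(graph$capillary_ids == capillary_id)
  if (length(segs) == 0) stopf("no capillary named '%s'", capillary_id)
  lens <- graph$seg_len[segs]
  cum <- c(0, cumsum(lens))
  r <- stats::runif(n, 0, sum(lens))
  i <- findInterval(r, cum, rightmost.closed = TRUE)
  i[i > length(segs)] <- length(segs)
  data.frame(segment = segs[i], arc_pos = r - cum[i])
}
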