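#' Capillary graph: polyline vessel network with somata and blockages
#'
#' A `capillary_graph` stores one image's capillary geometry as a set of
#' polyline segments (coordinates in micrometres), a partition of segments
#' into named capillaries, the axis-aligned field bounds, and two kinds of
#' on-vessel annotations: pericyte somata (with a visibility flag; positions
#' denote the soma mid-point) and blockage sites. Segment ends that share a
#' coordinate are treated as one node, which defines the network adjacency.
#'
#' Arc positions are measured in micrometres from the first point of the
#' owning segment's polyline.
#'
#' @param segments list of numeric matrices, one polyline per segment; each
#'   matrix has >= 2 rows and 2 or 3 columns (x, y\[, z\] in um).
#' @param capillary_ids character vector, one id per segment, naming the
#'   capillary each segment belongs to.
#' @param field_bounds numeric matrix with rows `min` and `max` and one
#'   column per coordinate; defaults to the bounding box of the polylines.
#' @param somata data frame with columns `segment` (1-based segment index),
#'   `arc_pos` (um from segment start) and `visible` (logical).
#' @param blockages data frame with columns `segment` and `arc_pos`.
#' @return an object of class `capillary_graph`.
#' @examples
#' seg <- list(cbind(x = c(0, 60), y = c(0, 0)))
#' g <- capillary_graph(seg, "cap1",
#'   somata = data.frame(segment = 1, arc_pos = 30, visible = TRUE))
#' nearest_soma_distance(g, point_on_vessel(1, 33.6))
#' @export
capillary_graph <- function(segments, capillary_ids,
                            field_bounds = NULL,
                            somata = NULL, blockages = NULL) {
  if (!is.list(segments) || length(segments) == 0) {
    stopf("`segments` must be a non-empty list of polyline matrices")
  }
  segments <- lapply(segments, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) < 2 || !(ncol(m) %in% c(2, 3))) {
      stopf("each polyline needs >= 2 points with 2 or 3 coordinates")
    }
    m
  })
  ndim <- unique(vapply(segments, ncol, 0L))
  if (length(ndim) != 1) stopf("all polylines must share a dimensionality")
  capillary_ids <- as.character(capillary_ids)
  if (length(capillary_ids) != length(segments)) {
    stopf("`capillary_ids` must name one capillary per segment")
  }
  seg_len <- vapply(segments, polyline_length, 0)
  if (any(seg_len <= 0)) stopf("every polyline must have positive length")

  somata <- normalize_annotation(somata, seg_len, visible = TRUE)
  blockages <- normalize_annotation(blockages, seg_len, visible = NA)
  blockages$visible <- NULL

  pts <- do.call(rbind, segments)
  if (is.null(field_bounds)) {
    field_bounds <- rbind(min = apply(pts, 2, min), max = apply(pts, 2, max))
  } else {
    field_bounds <- as.matrix(field_bounds)
    if (any(sweep(pts, 2, field_bounds["min", ], "<") - 1e-9 > 0) ||
        any(sweep(pts, 2, field_bounds["max", ], ">") - 1e-9 > 0)) {
      stopf("`field_bounds` must contain all polyline points")
    }
  }

  g <- structure(
    list(segments = segments, capillary_ids = capillary_ids,
         seg_len = seg_len, field_bounds = field_bounds,
         somata = somata, blockages = blockages),
    class = "capillary_graph")
  g <- add_topology(g)
  g
}

polyline_length <- function(m) {
  d <- diff(m)
  sum(sqrt(rowSums(d^2)))
}

normalize_annotation <- function(df, seg_len, visible) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    return(data.frame(segment = integer(), arc_pos = double(),
                      visible = logical()))
  }
  df <- as.data.frame(df)
  if (!all(c("segment", "arc_pos") %in% names(df))) {
    stopf("annotations need `segment` and `arc_pos` columns")
  }
  if (is.null(df$visible)) df$visible <- TRUE
  df$segment <- as.integer(df$segment)
  if (any(df$segment < 1 | df$segment > length(seg_len))) {
    stopf("annotation references a segment that does not exist")
  }
  bad <- df$arc_pos < -1e-9 | df$arc_pos > seg_len[df$segment] + 1e-9
  if (any(bad)) stopf("annotation arc position lies outside its segment")
  df$arc_pos <- pmin(pmax(df$arc_pos, 0), seg_len[df$segment])
  rownames(df) <- NULL
  df[c("segment", "arc_pos", "visible")]
}

# Merge coincident segment endpoints into nodes and precompute the
# node-to-node geodesic distance matrix (segments are the edges, weighted
# by arc length).
add_topology <- function(g, tol = 1e-6) {
  ends <- do.call(rbind, lapply(g$segments, function(m) m[c(1, nrow(m)), ]))
  key <- apply(round(ends / tol) * tol, 1, paste, collapse = ",")
  node_id <- match(key, unique(key))
  g$seg_nodes <- matrix(node_id, ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("start", "end")))
  g$n_nodes <- max(node_id)
  edges <- as.vector(t(g$seg_nodes))
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  ig <- igraph::add_edges(ig, edges)
  igraph::E(ig)$weight <- g$seg_len
  g$node_dist <- igraph::distances(ig, weights = igraph::E(ig)$weight)
  comp <- igraph::components(ig)$membership
  g$seg_component <- comp[g$seg_nodes[, "start"]]
  g
}

#' Reference a point on a vessel segment
#'
#' @param segment 1-based segment index.
#' @param arc_pos arc position in um from the segment's first point.
#' @return a `point_on_vessel` list.
#' @export
point_on_vessel <- function(segment, arc_pos) {
  structure(list(segment = as.integer(segment), arc_pos = as.numeric(arc_pos)),
            class = "point_on_vessel")
}

as_point <- function(p) {
  if (inherits(p, "point_on_vessel")) return(p)
  if (is.list(p) && all(c("segment", "arc_pos") %in% names(p))) {
    return(point_on_vessel(p$segment, p$arc_pos))
  }
  if (is.numeric(p) && length(p) == 2) return(point_on_vessel(p[1], p[2]))
  stopf("cannot interpret object as a point on a vessel")
}

check_point <- function(g, p) {
  p <- as_point(p)
  if (p$segment < 1 || p$segment > length(g$segments)) {
    stopf("point references segment %d, which does not exist", p$segment)
  }
  if (p$arc_pos < -1e-9 || p$arc_pos > g$seg_len[p$segment] + 1e-9) {
    stopf("arc position %.3f um lies outside segment %d (length %.3f um)",
          p$arc_pos, p$segment, g$seg_len[p$segment])
  }
  p$arc_pos <- min(max(p$arc_pos, 0), g$seg_len[p$segment])
  p
}

#' @export
print.capillary_graph <- function(x, ...) {
  cat(sprintf(
    "<capillary_graph> %d segments in %d capillaries, total length %.1f um\n",
    length(x$segments), length(unique(x$capillary_ids)),
    sum(x$seg_len)))
  cat(sprintf("  somata: %d (%d visible)   blockages: %d\n",
              nrow(x$somata), sum(x$somata$visible), nrow(x$blockages)))
  invisible(x)
}

#' Total imaged arc length of one capillary
#'
#' @param graph a [capillary_graph()].
#' @param capillary_id capillary name.
#' @return length in um.
#' @export
capillary_length <- function(graph, capillary_id) {
  idx <- which(graph$capillary_ids == capillary_id)
  if (length(idx) == 0) stopf("no capillary named '%s'", capillary_id)
  sum(graph$seg_len[idx])
}

#' Write a capillary graph to a directory of plain-text files
#'
#' The on-disk schema is one directory per image: `segments.csv`
#' (segment_id, point_index, x, y\[, z\]), `annotations.csv`
#' (kind, segment_id, arc_pos_um, visible) and `meta.json` (field bounds,
#' capillary id per segment, units). Segment ids are 0-based on disk.
#'
#' @param graph a [capillary_graph()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_capillary_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  segs <- do.call(rbind, lapply(seq_along(graph$segments), function(i) {
    m <- graph$segments[[i]]
    data.frame(segment_id = i - 1L, point_index = seq_len(nrow(m)) - 1L, m)
  }))
  names(segs)[-(1:2)] <- c("x", "y", "z")[seq_len(ncol(graph$segments[[1]]))]
  utils::write.csv(segs, file.path(dir, "segments.csv"), row.names = FALSE)
  ann <- rbind(
    if (nrow(graph$somata)) data.frame(kind = "soma",
      segment_id = graph$somata$segment - 1L,
      arc_pos_um = graph$somata$arc_pos, visible = graph$somata$visible),
    if (nrow(graph$blockages)) data.frame(kind = "blockage",
      segment_id = graph$blockages$segment - 1L,
      arc_pos_um = graph$blockages$arc_pos, visible = TRUE))
  if (is.null(ann)) {
    ann <- data.frame(kind = character(), segment_id = integer(),
                      arc_pos_um = double(), visible = logical())
  }
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  meta <- list(
    units = "um",
    field_bounds = list(min = unname(graph$field_bounds["min", ]),
                        max = unname(graph$field_bounds["max", ])),
    capillary_ids = graph$capillary_ids)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a capillary graph written by [write_capillary_graph()]
#'
#' @param dir directory containing `segments.csv`, `annotations.csv` and
#'   `meta.json`.
#' @return a [capillary_graph()].
#' @export
read_capillary_graph <- function(dir) {
  segs <- utils::read.csv(file.path(dir, "segments.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ann <- utils::read.csv(file.path(dir, "annotations.csv"))
  coord_cols <- intersect(c("x", "y", "z"), names(segs))
  ids <- sort(unique(segs$segment_id))
  polylines <- lapply(ids, function(id) {
    sub <- segs[segs$segment_id == id, ]
    as.matrix(sub[order(sub$point_index), coord_cols])
  })
  somata <- ann[ann$kind == "soma", ]
  blockages <- ann[ann$kind == "blockage", ]
  capillary_graph(
    polylines, meta$capillary_ids,
    field_bounds = rbind(min = meta$field_bounds$min,
                         max = meta$field_bounds$max),
    somata = if (nrow(somata)) data.frame(segment = somata$segment_id + 1L,
      arc_pos = somata$arc_pos_um, visible = as.logical(somata$visible)),
    blockages = if (nrow(blockages)) data.frame(
      segment = blockages$segment_id + 1L, arc_pos = blockages$arc_pos_um))
}
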