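# Seeded generator of the study's full data structure: capillary beds,
# pericytes, blockages, lumen profiles, diameter pairs and ventricular ROI
# maps under sham / ischaemia / ischaemia + adenosine conditions.

#' Generate one synthetic capillary bed
#'
#' Parallel capillaries span the square field, with occasional orthogonal
#' connector capillaries between adjacent parallels. Pericyte somata are
#' placed along each capillary with gamma-distributed inter-soma gaps at
#' the configured mean and CV; a fraction of capillaries (92% of parallels,
#' 66% of connectors by default) receives somata at all. All somata fall
#' inside the field and are flagged visible.
#'
#' @param cfg a [study_config()].
#' @param seed integer seed (same cfg + seed gives an identical bed).
#' @return a [capillary_graph()] with somata and no blockages.
#' @export
generate_bed <- function(cfg = study_config(), seed = NULL) {
  validate_config(cfg)
  with_seed(seed, {
    L <- cfg$field_size
    ncap <- cfg$capillaries_per_image
    spacing <- L / ncap
    if (spacing <= 0) stopf("field too small for one capillary")
    xs <- (seq_len(ncap) - 0.5) * spacing

    # connectors between adjacent parallel pairs
    conn <- data.frame(left = integer(), y = double())
    for (i in seq_len(max(ncap - 1, 0))) {
      if (stats::runif(1) < cfg$connector_prob) {
        conn <- rbind(conn, data.frame(left = i,
                                       y = stats::runif(1, 0.05 * L,
                                                        0.95 * L)))
      }
    }

    segments <- list()
    capillary_ids <- character()
    cap_segment_start <- list()  # cumulative arc offset per segment
    for (i in seq_len(ncap)) {
      ys <- sort(unique(c(0, L,
                          conn$y[conn$left == i | conn$left == i - 1L])))
      for (k in seq_len(length(ys) - 1)) {
        segments[[length(segments) + 1]] <-
          cbind(x = c(xs[i], xs[i]), y = c(ys[k], ys[k + 1]))
        capillary_ids <- c(capillary_ids, sprintf("cap%02d", i))
      }
    }
    for (j in seq_len(nrow(conn))) {
      i <- conn$left[j]
      segments[[length(segments) + 1]] <-
        cbind(x = c(xs[i], xs[i + 1]), y = rep(conn$y[j], 2))
      capillary_ids <- c(capillary_ids, sprintf("con%02d", j))
    }

    seg_len <- vapply(segments, polyline_length, 0)
    somata <- data.frame(segment = integer(), arc_pos = double(),
                         visible = logical())
    for (cap in unique(capillary_ids)) {
      segs <- which(capillary_ids == cap)
      total <- sum(seg_len[segs])
      is_conn <- startsWith(cap, "con")
      coverage <- cfg$soma_coverage[[if (is_conn) "connector" else "parallel"]]
      if (stats::runif(1) >= coverage) next
      pos <- if (is_conn) {
        stats::runif(1, 0, total)  # one contact on a short connector
      } else {
        soma_positions(total, cfg$intersoma_mean, cfg$intersoma_cv)
      }
      if (length(pos) == 0) next
      loc <- capillary_arc_to_segment(pos, segs, seg_len)
      somata <- rbind(somata, data.frame(segment = loc$segment,
                                         arc_pos = loc$arc_pos,
                                         visible = TRUE))
    }
    capillary_graph(segments, capillary_ids,
                    field_bounds = rbind(min = c(0, 0), max = c(L, L)),
                    somata = somata)
  })
}

# renewal-style soma placement along one capillary of given length
soma_positions <- function(total, mean_gap, cv) {
  shape <- 1 / cv^2
  scale <- mean_gap * cv^2
  pos <- stats::runif(1, 0, mean_gap)
  out <- numeric()
  while (pos <= total) {
    out <- c(out, pos)
    pos <- pos + stats::rgamma(1, shape = shape, scale = scale)
  }
  out
}

# map capillary-level arc positions to (segment index, within-segment arc)
capillary_arc_to_segment <- function(pos, segs, seg_len) {
  cum <- c(0, cumsum(seg_len[segs]))
  i <- findInterval(pos, cum, rightmost.closed = TRUE)
  i[i > length(segs)] <- length(segs)
  list(segment = segs[i], arc_pos = pmin(pos - cum[i], seg_len[segs][i]))
}

segment_arc_to_capillary <- function(graph, seg, arc) {
  cap <- graph$capillary_ids[seg]
  segs <- which(graph$capillary_ids == cap)
  cum <- c(0, cumsum(graph$seg_len[segs]))
  cum[match(seg, segs)] + arc
}

#' Apply an experimental condition to a capillary bed
#'
#' Each capillary is blocked independently with the condition's blockage
#' probability. In `"associated"` placement the blockage sits at an offset
#' from a randomly chosen soma on the blocked capillary, drawn from a
#' half-normal (or exponential) distribution scaled so its median equals
#' the configured value; capillaries without somata fall back to uniform
#' placement. In `"random"` placement blockages are uniform over the
#' capillary arc length -- exactly the generative counterpart of the
#' random-placement null model. One diameter pair per soma and one noisy
#' sigmoid lumen profile per blockage are synthesized.
#'
#' @param graph a [capillary_graph()] from [generate_bed()].
#' @param condition `"sham"`, `"ischaemia"` or `"ischaemia_adenosine"`.
#' @param cfg a [study_config()].
#' @param seed integer seed.
#' @param placement `"associated"` (default) or `"random"`.
#' @return list with `graph` (blockages added), `diameters` (data frame of
#'   diameter pairs), `profiles` (list of [lumen_profile()], one per
#'   blockage, with attribute `block_arc` giving the true block position)
#'   and `condition`.
#' @export
assign_condition <- function(graph, condition, cfg = study_config(),
                             seed = NULL,
                             placement = c("associated", "random")) {
  placement <- match.arg(placement)
  condition <- match.arg(condition, CONDITIONS)
  validate_config(cfg)
  if (nrow(graph$somata) == 0) stopf("graph has no somata")
  with_seed(seed, {
    p <- cfg$p_block[[condition]]
    caps <- unique(graph$capillary_ids)
    blockages <- data.frame(segment = integer(), arc_pos = double())
    for (cap in caps) {
      if (stats::runif(1) >= p) next
      segs <- which(graph$capillary_ids == cap)
      total <- sum(graph$seg_len[segs])
      soma_rows <- soma_candidates(graph, cap)
      if (placement == "random" || length(soma_rows) == 0) {
        pos <- stats::runif(1, 0, total)
      } else {
        row <- soma_rows[sample.int(length(soma_rows), 1)]
        s_arc <- segment_arc_to_capillary(graph, graph$somata$segment[row],
                                          graph$somata$arc_pos[row])
        off <- draw_block_offset(1, cfg)
        cand <- c(s_arc - off, s_arc + off)
        ok <- cand >= 0 & cand <= total
        pos <- if (any(ok)) {
          keep <- which(ok)
          cand[keep[sample.int(length(keep), 1)]]
        } else {
          min(max(cand[sample.int(2, 1)], 0), total)
        }
      }
      loc <- capillary_arc_to_segment(pos, segs, graph$seg_len)
      blockages <- rbind(blockages, data.frame(segment = loc$segment,
                                               arc_pos = loc$arc_pos))
    }
    graph$blockages <- normalize_annotation(blockages, graph$seg_len,
                                            visible = NA)
    graph$blockages$visible <- NULL

    n_pairs <- sum(graph$somata$visible)
    diameters <- generate_diameter_pairs(condition, n_pairs, cfg)
    blocked_caps <- unique(graph$capillary_ids[graph$blockages$segment])
    diameters$blockage_associated <-
      graph$capillary_ids[graph$somata$segment[graph$somata$visible]] %in%
      blocked_caps

    profiles <- lapply(seq_len(nrow(graph$blockages)), function(i) {
      synth_profile(cfg)
    })
    list(graph = graph, diameters = diameters, profiles = profiles,
         condition = condition)
  })
}

draw_block_offset <- function(n, cfg) {
  m <- cfg$block_distance_median
  if (cfg$block_offset_dist == "half_normal") {
    abs(stats::rnorm(n, 0, m / stats::qnorm(0.75)))
  } else {
    stats::rexp(n, rate = log(2) / m)
  }
}

# noisy sigmoid lumen profile with the block at the window centre
synth_profile <- function(cfg) {
  pr <- cfg$profile
  s <- seq(0, pr$length, by = pr$step)
  s0 <- pr$length / 2
  k <- pr$width_10_90 / (2 * log(9))
  signal <- 1 / (1 + exp((s - s0) / k))
  intensity <- pr$background + signal + stats::rnorm(length(s), 0,
                                                     pr$noise_sd)
  p <- lumen_profile(s, pmax(intensity, 0), background = pr$background)
  attr(p, "block_arc") <- s0
  p
}

#' Draw synthetic soma/upstream diameter pairs
#'
#' Independent draws from the condition's configured soma-diameter and
#' diameter-ratio distributions (normal, truncated at 0.3 um / ratio 0.05);
#' the upstream diameter is d_soma / ratio.
#'
#' @param condition condition name.
#' @param n number of pairs.
#' @param cfg a [study_config()].
#' @param seed optional integer seed.
#' @return data frame with columns `condition`, `d_soma`, `d_upstream`,
#'   `blockage_associated` (FALSE placeholder).
#' @export
generate_diameter_pairs <- function(condition, n, cfg = study_config(),
                                    seed = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  with_seed(seed, {
    ds <- cfg$d_soma[[condition]]
    rt <- cfg$ratio[[condition]]
    d_soma <- truncated_normal(n, ds[["mean"]], ds[["sd"]], lower = 0.3)
    ratio <- truncated_normal(n, rt[["mean"]], rt[["sd"]], lower = 0.05)
    data.frame(condition = condition, d_soma = d_soma,
               d_upstream = d_soma / ratio, blockage_associated = FALSE)
  })
}

truncated_normal <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= lower)) {
    i <- x <= lower
    x[i] <- stats::rnorm(sum(i), mean, sd)
  }
  x
}

#' Generate one heart's 12-ROI ventricular perfusion map
#'
#' Baseline intensity 1 with a posterior-wall elevation in ROIs 4-6 and the
#' condition's risk-zone multiplier in ROIs 7-10, under multiplicative
#' log-normal heart-level and ROI-level noise.
#'
#' @param condition condition name.
#' @param cfg a [study_config()].
#' @param seed optional integer seed.
#' @param heart_id identifier for the output table.
#' @return a [roi_table()] data frame.
#' @export
generate_ventricle_map <- function(condition, cfg = study_config(),
                                   seed = NULL, heart_id = "heart1") {
  condition <- match.arg(condition, CONDITIONS)
  with_seed(seed, {
    shape <- rep(1, 12)
    shape[4:6] <- shape[4:6] * cfg$roi$posterior_elevation
    shape[7:10] <- shape[7:10] * cfg$roi$risk_multiplier[[condition]]
    heart_f <- exp(stats::rnorm(1, 0, cfg$roi$noise_sd_heart))
    roi_f <- exp(stats::rnorm(12, 0, cfg$roi$noise_sd_roi))
    roi_table(heart_id, condition, shape * heart_f * roi_f)
  })
}

#' Generate a full on-disk synthetic study
#'
#' Writes, for each condition and heart: one ROI row set, and per image
#' stack a capillary-graph directory plus one lumen-profile CSV per
#' blockage; cohort-level `rois.csv` and `diameters.csv`; and a
#' `manifest.json` recording the configuration, the master seed and every
#' derived artifact seed, sufficient to replay the run exactly.
#'
#' @param cfg a [study_config()].
#' @param seed master integer seed.
#' @param out_dir destination directory.
#' @param placement blockage placement mode (see [assign_condition()]).
#' @return the manifest, invisibly.
#' @export
generate_study <- function(cfg = study_config(), seed = 1,
                           out_dir = "periflow_study",
                           placement = c("associated", "random")) {
  placement <- match.arg(placement)
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stopf("destination '%s' is not writable",
                                          out_dir)
  rois <- list()
  diameters <- list()
  stacks <- list()
  for (cond in names(cfg$hearts)) {
    for (h in seq_len(cfg$hearts[[cond]])) {
      heart_id <- sprintf("%s_heart%02d", cond, h)
      roi_seed <- derive_seed(seed, "roi", heart_id)
      rois[[heart_id]] <- generate_ventricle_map(cond, cfg, roi_seed,
                                                 heart_id)
      for (st in seq_len(cfg$stacks_per_heart)) {
        stack_id <- sprintf("%s_stack%02d", heart_id, st)
        bed_seed <- derive_seed(seed, "bed", stack_id)
        cond_seed <- derive_seed(seed, "cond", stack_id)
        bed <- generate_bed(cfg, bed_seed)
        art <- assign_condition(bed, cond, cfg, cond_seed, placement)
        stack_dir <- file.path(out_dir, cond, heart_id, stack_id)
        write_capillary_graph(art$graph, file.path(stack_dir, "graph"))
        for (i in seq_along(art$profiles)) {
          write_lumen_profile(art$profiles[[i]],
                              file.path(stack_dir,
                                        sprintf("profile%03d.csv", i)))
        }
        art$diameters$heart_id <- heart_id
        diameters[[stack_id]] <- art$diameters
        stacks[[stack_id]] <- list(
          condition = cond, heart_id = heart_id,
          dir = file.path(cond, heart_id, stack_id),
          bed_seed = bed_seed, cond_seed = cond_seed,
          n_profiles = length(art$profiles))
      }
    }
  }
  utils::write.csv(do.call(rbind, rois), file.path(out_dir, "rois.csv"),
                   row.names = FALSE)
  diam <- do.call(rbind, diameters)
  rownames(diam) <- NULL
  utils::write.csv(diam, file.path(out_dir, "diameters.csv"),
                   row.names = FALSE)
  manifest <- list(config = named_to_maps(unclass(cfg)), seed = seed,
                   placement = placement, stacks = stacks)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(manifest)
}
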