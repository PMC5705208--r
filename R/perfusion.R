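# Perfused-volume ROI quantification, transect counting and diameter-ratio
# analysis.

CONDITIONS <- c("sham", "ischaemia", "ischaemia_adenosine")

#' One heart's 12-ROI perfusion map
#'
#' Intensities are ordered clockwise around the left ventricle, index 1 at
#' the mid-septum. Returned in long format so cohorts can be stacked with
#' `rbind()`.
#'
#' @param heart_id heart identifier.
#' @param condition one of `"sham"`, `"ischaemia"`,
#'   `"ischaemia_adenosine"`.
#' @param intensities exactly 12 non-negative values (a.u.).
#' @return data frame with columns `heart_id`, `condition`, `roi`,
#'   `intensity`.
#' @export
roi_table <- function(heart_id, condition, intensities) {
  condition <- match.arg(condition, CONDITIONS)
  if (length(intensities) != 12 || any(!is.finite(intensities)) ||
      any(intensities < 0)) {
    stopf("a perfusion map needs exactly 12 non-negative intensities")
  }
  data.frame(heart_id = heart_id, condition = condition, roi = 1:12,
             intensity = as.numeric(intensities))
}

#' Normalize ROI perfusion maps within hearts and across a condition
#'
#' Each heart's 12 intensities are divided by that heart's maximum ROI
#' intensity; hearts are averaged per condition; finally each condition's
#' curves are rescaled by a single factor so the mean over ROIs 1-3 of the
#' reference equals 1. With `reference = "own"` (default) each condition
#' uses its own ROIs 1-3 mean (ROIs 1-3 lie outside the risk zone in all
#' conditions); `reference = "sham"` rescales every condition by the sham
#' factor.
#'
#' @param tables stacked [roi_table()] rows for one cohort.
#' @param reference `"own"` or `"sham"`.
#' @return list with `per_heart` (long data frame of normalized values)
#'   and `condition_means` (data frame of per-ROI mean and s.e.m. per
#'   condition).
#' @export
normalize_rois <- function(tables, reference = c("own", "sham")) {
  reference <- match.arg(reference)
  stopifnot(all(c("heart_id", "condition", "roi", "intensity") %in%
                  names(tables)))
  per_heart <- do.call(rbind, lapply(split(tables, tables$heart_id),
                                     function(h) {
    h <- h[order(h$roi), ]
    if (nrow(h) != 12) stopf("heart '%s' does not have 12 ROIs",
                             h$heart_id[1])
    if (max(h$intensity) <= 0) stopf("empty perfusion map for heart '%s'",
                                     h$heart_id[1])
    h$value <- h$intensity / max(h$intensity)
    h
  }))
  rownames(per_heart) <- NULL
  ref_factor <- function(cond) {
    sub <- per_heart[per_heart$condition == cond, ]
    cond_mean <- tapply(sub$value, sub$roi, mean)
    mean(cond_mean[as.character(1:3)])
  }
  for (cond in unique(per_heart$condition)) {
    f <- if (reference == "own") ref_factor(cond) else ref_factor("sham")
    sel <- per_heart$condition == cond
    per_heart$value[sel] <- per_heart$value[sel] / f
  }
  agg <- do.call(rbind, lapply(split(per_heart,
                                     per_heart[c("roi", "condition")],
                                     drop = TRUE), function(g) {
    data.frame(condition = g$condition[1], roi = g$roi[1],
               mean = mean(g$value), sem = sem(g$value))
  }))
  agg <- agg[order(agg$condition, agg$roi), ]
  rownames(agg) <- NULL
  list(per_heart = per_heart, condition_means = agg)
}

#' Risk-zone perfusion deficit and rescue
#'
#' Averages the normalized perfusion values over the risk-zone ROIs
#' (default 7-10) for each heart, summarizes per condition and reports the
#' percent deficit of ischaemia relative to sham and the percent increase
#' under adenosine relative to ischaemia, with gated two-group p-values.
#' Contrasts whose conditions are absent are skipped.
#'
#' @param normalized result of [normalize_rois()].
#' @param risk_rois ROI indices forming the risk zone (default `7:10`).
#' @return list with `per_heart` (risk-zone mean per heart),
#'   `condition_means`, `pct_deficit_ischaemia`, `pct_rescue_adenosine` and
#'   `tests` (list of `test_result`).
#' @export
risk_zone_deficit <- function(normalized, risk_rois = 7:10) {
  ph <- normalized$per_heart
  ph <- ph[ph$roi %in% risk_rois, ]
  per_heart <- do.call(rbind, lapply(split(ph, ph$heart_id), function(h) {
    data.frame(heart_id = h$heart_id[1], condition = h$condition[1],
               risk_mean = mean(h$value))
  }))
  rownames(per_heart) <- NULL
  cm <- tapply(per_heart$risk_mean, per_heart$condition, mean)
  cs <- tapply(per_heart$risk_mean, per_heart$condition, sem)
  condition_means <- data.frame(condition = names(cm), mean = as.numeric(cm),
                                sem = as.numeric(cs))
  vals <- function(cond) per_heart$risk_mean[per_heart$condition == cond]
  out <- list(per_heart = per_heart, condition_means = condition_means,
              pct_deficit_ischaemia = NA_real_,
              pct_rescue_adenosine = NA_real_, tests = list())
  if (all(c("sham", "ischaemia") %in% names(cm))) {
    out$pct_deficit_ischaemia <-
      100 * (1 - cm[["ischaemia"]] / cm[["sham"]])
    out$tests$ischaemia_vs_sham <- auto_compare(vals("ischaemia"),
                                                vals("sham"))
  }
  if (all(c("ischaemia", "ischaemia_adenosine") %in% names(cm))) {
    out$pct_rescue_adenosine <-
      100 * (cm[["ischaemia_adenosine"]] / cm[["ischaemia"]] - 1)
    out$tests$adenosine_vs_ischaemia <-
      auto_compare(vals("ischaemia_adenosine"), vals("ischaemia"))
  }
  out
}

#' Count perfused and blocked capillaries crossing a central transect
#'
#' Draws a line through the centre of the field perpendicular to the main
#' capillary axis and counts the capillaries whose polylines cross it. A
#' crossing capillary is counted as blocked when it carries a blockage
#' annotation (no flow beyond the block), otherwise as perfused.
#'
#' @param graph a [capillary_graph()].
#' @param image_id identifier recorded in the output.
#' @param condition condition label recorded in the output.
#' @param axis main capillary axis: `"auto"` (dominant segment direction),
#'   `"x"` or `"y"`.
#' @return data frame with columns `image_id`, `condition`, `n_perfused`,
#'   `n_blocked`.
#' @export
transect_counts <- function(graph, image_id = NA, condition = NA,
                            axis = c("auto", "x", "y")) {
  axis <- match.arg(axis)
  if (axis == "auto") {
    spans <- vapply(graph$segments, function(m) {
      abs(m[nrow(m), 1:2] - m[1, 1:2])
    }, numeric(2))
    axis <- if (sum(spans[1, ]) >= sum(spans[2, ])) "x" else "y"
  }
  ax <- if (axis == "x") 1 else 2
  centre <- mean(graph$field_bounds[, ax])
  blocked_caps <- unique(graph$capillary_ids[graph$blockages$segment])
  crossing <- vapply(unique(graph$capillary_ids), function(cap) {
    segs <- which(graph$capillary_ids == cap)
    coords <- unlist(lapply(graph$segments[segs], function(m) m[, ax]))
    min(coords) <= centre && max(coords) >= centre
  }, TRUE)
  caps <- unique(graph$capillary_ids)[crossing]
  n_blocked <- sum(caps %in% blocked_caps)
  data.frame(image_id = image_id, condition = condition,
             n_perfused = length(caps) - n_blocked, n_blocked = n_blocked)
}

#' Percentage of blocked capillaries per condition
#'
#' Per-image blocked fractions n_blocked / (n_blocked + n_perfused) are
#' averaged within each condition (images as units, unweighted) and
#' reported as a percentage with the s.e.m. over images.
#'
#' @param counts stacked [transect_counts()] rows (columns `image_id`,
#'   `condition`, `n_perfused`, `n_blocked`).
#' @return data frame with columns `condition`, `pct_blocked`, `sem`,
#'   `n_images`.
#' @export
blocked_fraction <- function(counts) {
  stopifnot(all(c("condition", "n_perfused", "n_blocked") %in% names(counts)))
  tot <- counts$n_perfused + counts$n_blocked
  if (any(tot < 1)) stopf("each image must cross at least one capillary")
  counts$frac <- counts$n_blocked / tot
  out <- do.call(rbind, lapply(split(counts, counts$condition), function(g) {
    data.frame(condition = g$condition[1],
               pct_blocked = 100 * mean(g$frac),
               sem = 100 * sem(g$frac), n_images = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Soma/upstream diameter-ratio analysis
#'
#' For each lumen-diameter pair (at a pericyte soma and ~10 um upstream)
#' the ratio d_soma / d_upstream is formed; condition means and s.e.m. are
#' reported for the ratio and the absolute soma diameter, along with the
#' percent reduction of mean soma diameter under ischaemia vs sham, the
#' percent increase under adenosine vs ischaemia, one-sample tests of the
#' ratio against 1 and gated pairwise between-condition tests (corrected
#' within the panel family).
#'
#' @param pairs data frame with columns `condition`, `d_soma`,
#'   `d_upstream` (um) and optionally `heart_id`, `blockage_associated`.
#' @return list with `per_condition` (data frame), `pct_dsoma_reduction_ischaemia`,
#'   `pct_dsoma_increase_adenosine`, `ratio_vs_1` and `between` (lists of
#'   `test_result`).
#' @export
diameter_ratio_analysis <- function(pairs) {
  stopifnot(all(c("condition", "d_soma", "d_upstream") %in% names(pairs)))
  bad <- !(pairs$d_upstream > 0) | !(pairs$d_soma > 0)
  if (any(bad)) {
    warnf("%d pair(s) with non-positive diameter excluded", sum(bad))
    pairs <- pairs[!bad, ]
  }
  pairs$ratio <- pairs$d_soma / pairs$d_upstream
  tab <- tapply(seq_len(nrow(pairs)), pairs$condition, function(i) i)
  if (any(vapply(tab, length, 0L) < 2)) {
    stopf("need >= 2 diameter pairs per condition")
  }
  per_condition <- do.call(rbind, lapply(names(tab), function(cond) {
    i <- tab[[cond]]
    data.frame(condition = cond, n = length(i),
               ratio_mean = mean(pairs$ratio[i]),
               ratio_sem = sem(pairs$ratio[i]),
               d_soma_mean = mean(pairs$d_soma[i]),
               d_soma_sem = sem(pairs$d_soma[i]))
  }))
  rownames(per_condition) <- NULL
  get <- function(cond, col) {
    per_condition[per_condition$condition == cond, col]
  }
  vals <- function(cond, col) pairs[pairs$condition == cond, col]
  out <- list(per_condition = per_condition,
              pct_dsoma_reduction_ischaemia = NA_real_,
              pct_dsoma_increase_adenosine = NA_real_,
              ratio_vs_1 = list(), between = list())
  for (cond in per_condition$condition) {
    out$ratio_vs_1[[cond]] <- one_sample_compare(vals(cond, "ratio"), mu = 1)
  }
  present <- per_condition$condition
  if (all(c("sham", "ischaemia") %in% present)) {
    out$pct_dsoma_reduction_ischaemia <-
      100 * (1 - get("ischaemia", "d_soma_mean") / get("sham", "d_soma_mean"))
    out$between$ischaemia_vs_sham <-
      auto_compare(vals("ischaemia", "ratio"), vals("sham", "ratio"))
  }
  if (all(c("ischaemia", "ischaemia_adenosine") %in% present)) {
    out$pct_dsoma_increase_adenosine <-
      100 * (get("ischaemia_adenosine", "d_soma_mean") /
               get("ischaemia", "d_soma_mean") - 1)
    out$between$adenosine_vs_ischaemia <-
      auto_compare(vals("ischaemia_adenosine", "ratio"),
                   vals("ischaemia", "ratio"))
  }
  if (length(out$between) > 0) {
    p_corr <- holm_correct(vapply(out$between, `[[`, 0, "p_raw"))
    for (i in seq_along(out$between)) {
      out$between[[i]]$p_corrected <- p_corr[i]
    }
  }
  out
}
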