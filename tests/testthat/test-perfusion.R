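test_that("ROI normalization matches hand arithmetic", {
  flat <- roi_table("h1", "sham", rep(2, 12))
  norm <- normalize_rois(flat)
  expect_equal(norm$per_heart$value, rep(1, 12))

  h <- roi_table("h2", "sham", c(2, 2, 2, 3, 3, 3, rep(2, 6)))
  norm2 <- normalize_rois(h)
  # max-normalized: 2/3 except ROIs 4-6; after the ROIs 1-3 rescale, 1 there
  expect_equal(norm2$per_heart$value[1:3], rep(1, 3))
  expect_equal(norm2$per_heart$value[4:6], rep(1.5, 3))
  expect_equal(norm2$per_heart$value[7:12], rep(1, 6))
})

test_that("normalization is invariant to per-heart intensity scale", {
  set.seed(51)
  raw <- runif(12, 1, 5)
  other <- runif(12, 1, 5)
  a <- normalize_rois(rbind(roi_table("h1", "ischaemia", raw),
                            roi_table("h2", "ischaemia", other)))
  b <- normalize_rois(rbind(roi_table("h1", "ischaemia", raw * 7.3),
                            roi_table("h2", "ischaemia", other)))
  expect_equal(a$per_heart$value[a$per_heart$heart_id == "h1"],
               b$per_heart$value[b$per_heart$heart_id == "h1"])
  expect_error(normalize_rois(roi_table("h0", "sham", rep(0, 12))),
               "empty perfusion map")
})

test_that("risk-zone deficit is zero when conditions are identical", {
  vals <- c(1, 1, 1, 1.2, 1.2, 1.2, 1, 1, 1, 1, 1, 1)
  tabs <- rbind(
    roi_table("s1", "sham", vals), roi_table("s2", "sham", vals * 2),
    roi_table("s3", "sham", vals),
    roi_table("i1", "ischaemia", vals), roi_table("i2", "ischaemia", vals),
    roi_table("i3", "ischaemia", vals * 3))
  rz <- risk_zone_deficit(normalize_rois(tabs))
  expect_equal(rz$pct_deficit_ischaemia, 0, tolerance = 1e-12)
  expect_true(is.na(rz$pct_rescue_adenosine))
})

test_that("transect counting sees crossing capillaries and their blocks", {
  cfg <- study_config()
  g <- generate_bed(cfg, seed = 3)
  a <- assign_condition(g, "ischaemia", cfg, seed = 4)
  tc <- transect_counts(a$graph, image_id = "im1", condition = "ischaemia")
  # every parallel capillary spans the field and crosses the transect
  expect_gte(tc$n_perfused + tc$n_blocked, cfg$capillaries_per_image)
  blocked_caps <- unique(a$graph$capillary_ids[a$graph$blockages$segment])
  crossing_blocked <- vapply(blocked_caps, function(cap) {
    segs <- which(a$graph$capillary_ids == cap)
    ys <- unlist(lapply(a$graph$segments[segs], function(m) m[, 2]))
    min(ys) <= 80 && max(ys) >= 80
  }, TRUE)
  expect_equal(tc$n_blocked, sum(crossing_blocked))
})

test_that("blocked fractions average per-image fractions", {
  counts <- rbind(
    data.frame(image_id = 1, condition = "sham", n_perfused = 30,
               n_blocked = 0),
    data.frame(image_id = 2, condition = "ischaemia", n_perfused = 18,
               n_blocked = 12),
    data.frame(image_id = 3, condition = "ischaemia", n_perfused = 24,
               n_blocked = 6))
  bf <- blocked_fraction(counts)
  expect_equal(bf$pct_blocked[bf$condition == "sham"], 0)
  expect_equal(bf$pct_blocked[bf$condition == "ischaemia"],
               100 * mean(c(12 / 30, 6 / 30)))
  # condition mean lies between the per-image extremes
  expect_gte(bf$pct_blocked[bf$condition == "ischaemia"], 20)
  expect_lte(bf$pct_blocked[bf$condition == "ischaemia"], 40)
})

test_that("diameter-ratio analysis is exact algebra on condition means", {
  pairs <- rbind(
    data.frame(condition = "sham", d_soma = c(5, 6, 5.5, 4.5),
               d_upstream = c(5, 6, 5.5, 4.5)),
    data.frame(condition = "ischaemia", d_soma = c(3, 3.5, 3.25, 3.4),
               d_upstream = c(4, 4.2, 4.1, 4.0)))
  res <- suppressWarnings(diameter_ratio_analysis(pairs))
  sham <- res$per_condition[res$per_condition$condition == "sham", ]
  expect_equal(sham$ratio_mean, 1)
  expect_equal(res$pct_dsoma_reduction_ischaemia,
               100 * (1 - mean(c(3, 3.5, 3.25, 3.4)) /
                        mean(c(5, 6, 5.5, 4.5))))
  expect_true(all(c("ischaemia_vs_sham") %in% names(res$between)))
  # non-positive upstream diameters are excluded with a warning
  bad <- rbind(pairs, data.frame(condition = "sham", d_soma = 5,
                                 d_upstream = 0))
  expect_warning(diameter_ratio_analysis(bad), "excluded")
})

test_that("diameter ratio recovery at configured condition parameters", {
  cfg <- study_config()
  d <- rbind(generate_diameter_pairs("sham", 20, cfg, seed = 61),
             generate_diameter_pairs("ischaemia", 60, cfg, seed = 62),
             generate_diameter_pairs("ischaemia_adenosine", 60, cfg,
                                     seed = 63))
  res <- diameter_ratio_analysis(d)
  pc <- res$per_condition
  get <- function(cond, col) pc[pc$condition == cond, col]
  expect_lt(abs(get("sham", "ratio_mean") - 1.058),
            3 * get("sham", "ratio_sem"))
  expect_lt(abs(get("ischaemia", "ratio_mean") - 0.822),
            3 * get("ischaemia", "ratio_sem"))
  # sham ratio significantly above 1, ischaemia significantly below
  expect_lt(res$ratio_vs_1$sham$p_raw, 0.05)
  expect_lt(res$ratio_vs_1$ischaemia$p_raw, 0.05)
  expect_lt(res$between$ischaemia_vs_sham$p_corrected, 0.05)
})
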