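test_that("beds are reproducible and respect the configured geometry", {
  cfg <- study_config()
  g1 <- generate_bed(cfg, seed = 10)
  g2 <- generate_bed(cfg, seed = 10)
  expect_identical(g1$segments, g2$segments)
  expect_identical(g1$somata, g2$somata)
  g3 <- generate_bed(cfg, seed = 11)
  expect_false(identical(g1$somata, g3$somata))
  # all points inside the field
  pts <- do.call(rbind, g1$segments)
  expect_true(all(pts >= 0 & pts <= cfg$field_size))
  expect_equal(sum(startsWith(unique(g1$capillary_ids), "cap")),
               cfg$capillaries_per_image)
})

test_that("disabling connectors leaves isolated parallel capillaries", {
  cfg <- study_config(connector_prob = 0)
  g <- generate_bed(cfg, seed = 12)
  expect_equal(length(g$segments), cfg$capillaries_per_image)
  expect_true(all(startsWith(g$capillary_ids, "cap")))
  # no two segments share a node
  expect_equal(g$n_nodes, 2 * length(g$segments))
})

test_that("intersoma spacing on the default bed recovers the 60 um mean", {
  g <- generate_bed(study_config(), seed = 42)
  d <- intersoma_distances(g)
  expect_gt(length(d), 10)
  expect_lt(abs(mean(d) - 60), 3 * sd(d) / sqrt(length(d)))
})

test_that("conditions block capillaries at their configured rates", {
  cfg <- study_config()
  g <- generate_bed(cfg, seed = 13)
  none <- assign_condition(g, "sham", study_config(
    p_block = c(sham = 0, ischaemia = 0.4, ischaemia_adenosine = 0.3)),
    seed = 14)
  expect_equal(nrow(none$graph$blockages), 0)
  expect_length(none$profiles, 0)
  isch <- assign_condition(g, "ischaemia", cfg, seed = 15)
  expect_gt(nrow(isch$graph$blockages), 0)
  expect_length(isch$profiles, nrow(isch$graph$blockages))
  expect_equal(nrow(isch$diameters), sum(g$somata$visible))
  # reproducible
  isch2 <- assign_condition(g, "ischaemia", cfg, seed = 15)
  expect_identical(isch$graph$blockages, isch2$graph$blockages)
  expect_identical(isch$diameters, isch2$diameters)
})

test_that("associated placement concentrates blockages near somata", {
  cfg <- study_config()
  graphs <- lapply(1:15, function(i) {
    g <- generate_bed(cfg, seed = 900 + i)
    assign_condition(g, "ischaemia", cfg, seed = 950 + i)$graph
  })
  obs <- suppressWarnings(observed_distances(graphs))
  # order-statistic interval for the median of the configured half-normal
  n <- length(obs$distances)
  sigma <- cfg$block_distance_median / qnorm(0.75)
  pl <- qbeta(0.005, floor(n / 2), n - floor(n / 2) + 1)
  pu <- qbeta(0.995, ceiling(n / 2) + 1, n - ceiling(n / 2))
  expect_gt(obs$median, sigma * qnorm((1 + pl) / 2))
  expect_lt(obs$median, sigma * qnorm((1 + pu) / 2))
})

test_that("random placement matches the pooled null distribution", {
  cfg <- study_config()
  graphs <- lapply(1:15, function(i) {
    g <- generate_bed(cfg, seed = 1900 + i)
    assign_condition(g, "ischaemia", cfg, seed = 1950 + i,
                     placement = "random")$graph
  })
  obs <- suppressWarnings(observed_distances(graphs))
  # pool per blocked capillary (each blockage is one uniform draw on its
  # own capillary, so capillaries carry equal weight here)
  cdfs <- list()
  for (g in graphs) {
    for (cap in unique(g$capillary_ids[g$blockages$segment])) {
      cdf <- tryCatch(image_null_cdf(g, cap), error = function(e) NULL)
      if (!is.null(cdf)) cdfs[[length(cdfs) + 1]] <- cdf
    }
  }
  res <- compare_to_null(obs$distances, pool_cdfs(cdfs))
  expect_gt(res$p_one_sample, 0.01)
})

test_that("ventricle maps follow the configured shape when noiseless", {
  cfg <- study_config(roi = list(posterior_elevation = 1.2,
                                 risk_multiplier = c(sham = 1,
                                                     ischaemia = 0.51,
                                                     ischaemia_adenosine = 0.8),
                                 noise_sd_heart = 0, noise_sd_roi = 0))
  sham <- generate_ventricle_map("sham", cfg, seed = 1)
  expect_equal(sham$intensity, c(1, 1, 1, 1.2, 1.2, 1.2, rep(1, 6)))
  isch <- generate_ventricle_map("ischaemia", cfg, seed = 1)
  expect_equal(isch$intensity[7:10], rep(0.51, 4))
  expect_equal(isch$intensity[7:10] / sham$intensity[7:10], rep(0.51, 4))
})

test_that("a generated study writes a replayable dataset", {
  cfg <- study_config(hearts = c(sham = 1, ischaemia = 1,
                                 ischaemia_adenosine = 1),
                      stacks_per_heart = 1, capillaries_per_image = 8)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_study(cfg, seed = 5, out_dir = dir1)
  m2 <- generate_study(cfg, seed = 5, out_dir = dir2)
  expect_equal(m1$stacks, m2$stacks)
  for (f in c("rois.csv", "diameters.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  st <- m1$stacks[[1]]
  g <- read_capillary_graph(file.path(dir1, st$dir, "graph"))
  expect_s3_class(g, "capillary_graph")
  # manifest replay: regenerating from recorded seeds gives the same graph
  bed <- generate_bed(cfg, m1$stacks[[1]]$bed_seed)
  art <- assign_condition(bed, m1$stacks[[1]]$condition, cfg,
                          m1$stacks[[1]]$cond_seed)
  expect_equal(g$somata, art$graph$somata)
  expect_equal(g$blockages, art$graph$blockages)
  # different seed changes the data but not the schema
  dir3 <- withr::local_tempdir()
  m3 <- generate_study(cfg, seed = 6, out_dir = dir3)
  expect_setequal(names(m3$stacks), names(m1$stacks))
  expect_false(identical(readLines(file.path(dir1, "rois.csv")),
                         readLines(file.path(dir3, "rois.csv"))))
})

test_that("study configuration validates and round-trips", {
  expect_error(study_config(p_block = c(sham = 2, ischaemia = 0.4,
                                        ischaemia_adenosine = 0.3)))
  expect_error(study_config(nonsense = 1), "unknown config")
  cfg <- study_config(intersoma_cv = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  cfg2 <- read_study_config(path)
  expect_equal(cfg2$intersoma_cv, 0.25)
  expect_equal(cfg2$p_block, cfg$p_block)
  expect_equal(cfg2$ratio, cfg$ratio)
})
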