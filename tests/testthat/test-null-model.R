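test_that("single-soma capillary reproduces the closed-form density", {
  # L = 60, soma at A = 10: density 2/L below A, 1/L on (A, L - A), 0 above
  g <- straight_capillary(60, soma_arcs = 10)
  cdf <- image_null_cdf(g, "cap1")
  expect_equal(cdf_prob(cdf, 10), 1 / 3)
  expect_equal(cdf_prob(cdf, 50), 1)
  expect_equal(cdf_prob(cdf, 5), 2 * 5 / 60)
  expect_equal(cdf_prob(cdf, 30), 1 / 3 + 20 / 60)
  expect_equal(max(cdf$breakpoints), 50)
})

test_that("a centred soma gives a uniform distance distribution", {
  g <- straight_capillary(60, soma_arcs = 30)
  cdf <- image_null_cdf(g, "cap1")
  expect_equal(cdf_prob(cdf, 15), 0.5)
  expect_equal(quantile(cdf, 0.5), 15)
})

test_that("two-soma capillary matches the discretization oracle", {
  g <- straight_capillary(60, soma_arcs = c(10, 40))
  cdf <- image_null_cdf(g, "cap1")
  qs <- cdf_query_points(cdf)
  d <- y_oracle_distance(seq(0, 60, by = 0.01), 1, c(1, 1), c(10, 40))
  est <- oracle_cdf_from_edges(d, 0.01, 60, qs)
  expect_lt(max(abs(cdf_prob(cdf, qs) - est)), 1e-6)
})

test_that("null CDFs are proper distributions with tight support", {
  set.seed(31)
  for (rep in 1:15) {
    ns <- sample(1:3, 1)
    L <- runif(1, 30, 100)
    g <- straight_capillary(L, soma_arcs = runif(ns, 0, L))
    cdf <- image_null_cdf(g, "cap1")
    expect_equal(cdf$cum_probs[1], 0)
    expect_equal(cdf$cum_probs[length(cdf$cum_probs)], 1)
    expect_true(all(diff(cdf$cum_probs) >= -1e-12))
    # support ends at the largest attainable nearest-soma distance
    a <- sort(g$somata$arc_pos)
    dmax <- max(c(a[1], L - a[length(a)], diff(a) / 2))
    expect_equal(max(cdf$breakpoints), dmax, tolerance = 1e-9)
  }
})

test_that("degenerate capillaries signal", {
  g <- straight_capillary(60, soma_arcs = 10, visible = FALSE)
  expect_error(image_null_cdf(g, "cap1"), "degenerate geometry")
  expect_error(image_null_cdf(straight_capillary(60, 10), "nope"),
               "no capillary")
})

test_that("pooling averages CDFs pointwise with equal image weight", {
  u10 <- distance_cdf(c(0, 10), c(0, 1))
  u30 <- distance_cdf(c(0, 30), c(0, 1))
  same <- pool_cdfs(list(u10, u10))
  expect_equal(cdf_prob(same, c(2, 5, 9)), cdf_prob(u10, c(2, 5, 9)))
  mix <- pool_cdfs(list(u10, u30))
  expect_equal(cdf_prob(mix, 10), (1 + 1 / 3) / 2)
  # linearity: order-invariant and associative under equal weights
  u20 <- distance_cdf(c(0, 20), c(0, 1))
  p1 <- pool_cdfs(list(u10, u20, u30))
  p2 <- pool_cdfs(list(u30, u10, u20))
  qs <- seq(0, 30, by = 0.5)
  expect_equal(cdf_prob(p1, qs), cdf_prob(p2, qs))
  w <- pool_cdfs(list(pool_cdfs(list(u10, u20)), u30), weights = c(2, 1))
  expect_equal(cdf_prob(w, qs), cdf_prob(p1, qs))
  expect_error(pool_cdfs(list()), "no images")
})

test_that("equi-probability sampling returns midpoint quantiles", {
  u30 <- linear_null(30)
  expect_equal(equiprobability_sample(u30, 4), c(3.75, 11.25, 18.75, 26.25))
  expect_equal(equiprobability_sample(u30, 1), 15)
  expect_equal(equiprobability_sample(u30, 3, convention = "right"),
               c(10, 20, 30))
  expect_error(equiprobability_sample(u30, 0), "invalid n")
  # sup-norm bound: the sample's empirical CDF deviates by at most 1/(2n)
  g <- straight_capillary(77, soma_arcs = c(13, 48))
  cdf <- image_null_cdf(g, "cap1")
  n <- 42
  smp <- equiprobability_sample(cdf, n)
  qs <- cdf_query_points(cdf)
  expect_lte(max(abs(stats::ecdf(smp)(qs) - cdf_prob(cdf, qs))),
             1 / (2 * n) + 1e-9)
})

test_that("the linear null rises to 1 at half the soma spacing", {
  lin <- linear_null(30)
  expect_equal(cdf_prob(lin, 30), 1)
  expect_equal(cdf_prob(lin, 29.99), 29.99 / 30)
  expect_equal(quantile(lin, 0.5), 15)
  expect_error(linear_null(0), "invalid spacing")
  # a long capillary with 60 um-spaced somata approaches the linear ideal
  g <- straight_capillary(6000, soma_arcs = seq(30, 5970, by = 60))
  cdf <- image_null_cdf(g, "cap1")
  qs <- seq(0, 30, by = 0.05)
  expect_lt(max(abs(cdf_prob(cdf, qs) - cdf_prob(lin, qs))), 1e-3)
})

test_that("image truncation shifts pooled null mass downward", {
  set.seed(5)
  cfg <- study_config()
  graphs <- lapply(1:8, function(i) {
    g <- generate_bed(cfg, seed = 500 + i)
    assign_condition(g, "ischaemia", cfg, seed = 600 + i)$graph
  })
  nm <- suppressWarnings(null_model(graphs))
  expect_lt(nm$predicted_median, 30)
  expect_s3_class(nm$pooled, "distance_cdf")
  expect_equal(nm$samples, sort(nm$samples))
  expect_equal(nm$predicted_median, unname(quantile(nm$pooled, 0.5)))
})

test_that("distance CDFs round-trip through CSV", {
  g <- straight_capillary(60, soma_arcs = c(10, 40))
  cdf <- image_null_cdf(g, "cap1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_cdf(cdf, path)
  cdf2 <- read_distance_cdf(path)
  expect_equal(cdf2$breakpoints, cdf$breakpoints)
  expect_equal(cdf2$cum_probs, cdf$cum_probs)
})
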