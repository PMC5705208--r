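test_that("arc_distance handles collinear points, identity and branches", {
  g <- straight_capillary(60)
  expect_equal(arc_distance(g, point_on_vessel(1, 10), point_on_vessel(1, 25)),
               15)
  expect_equal(arc_distance(g, point_on_vessel(1, 33), point_on_vessel(1, 33)),
               0)
  gy <- y_graph(c(20, 20, 20))
  expect_equal(arc_distance(gy, point_on_vessel(2, 5), point_on_vessel(3, 5)),
               10)
  # a shortcut edge beats the long way around a tortuous segment
  arc_len <- 2 * sqrt(50^2 + 80^2)
  ring <- capillary_graph(
    list(rbind(c(0, 0), c(50, 80), c(100, 0)),
         rbind(c(0, 0), c(0, 5), c(100, 5), c(100, 0))),
    c("cap1", "cap2"))
  expect_equal(arc_distance(ring, point_on_vessel(1, 1),
                            point_on_vessel(1, arc_len - 1)),
               1 + 110 + 1)
})

test_that("points on disconnected components signal unreachable", {
  g <- capillary_graph(list(cbind(c(0, 10), c(0, 0)),
                            cbind(c(0, 10), c(50, 50))),
                       c("cap1", "cap2"))
  expect_error(arc_distance(g, point_on_vessel(1, 5), point_on_vessel(2, 5)),
               "unreachable")
})

test_that("arc_distance is a metric on random connected graphs", {
  set.seed(11)
  for (rep in 1:20) {
    g <- y_graph(runif(3, 5, 40),
                 soma_seg = sample(1:3, 2, replace = TRUE),
                 soma_arc = c(1, 2))
    pts <- lapply(1:3, function(i) {
      seg <- sample(1:3, 1)
      point_on_vessel(seg, runif(1, 0, g$seg_len[seg]))
    })
    dab <- arc_distance(g, pts[[1]], pts[[2]])
    dba <- arc_distance(g, pts[[2]], pts[[1]])
    dac <- arc_distance(g, pts[[1]], pts[[3]])
    dcb <- arc_distance(g, pts[[3]], pts[[2]])
    expect_equal(dab, dba)
    expect_gte(dac + dcb, dab - 1e-9)
    expect_equal(arc_distance(g, pts[[1]], pts[[1]]), 0)
  }
})

test_that("nearest_soma_distance finds the closest visible soma", {
  g <- straight_capillary(60, soma_arcs = 30)
  res <- nearest_soma_distance(g, point_on_vessel(1, 33.6))
  expect_equal(res$distance, 3.6)
  expect_equal(nearest_soma_distance(g, point_on_vessel(1, 30))$distance, 0)
  g2 <- straight_capillary(60, soma_arcs = c(0, 60))
  res2 <- nearest_soma_distance(g2, point_on_vessel(1, 25))
  expect_equal(res2$distance, 25)
  expect_equal(res2$soma, 1)  # the soma at arc 0, by lowest index on ties
})

test_that("invisible somata are excluded and absence of somata signals", {
  g <- straight_capillary(60, soma_arcs = c(10, 50),
                          visible = c(FALSE, TRUE))
  expect_equal(nearest_soma_distance(g, point_on_vessel(1, 12))$distance, 38)
  g0 <- straight_capillary(60, soma_arcs = 10, visible = FALSE)
  expect_error(nearest_soma_distance(g0, point_on_vessel(1, 5)), "no soma")
})

test_that("nearest soma is a lower bound over all per-soma distances", {
  set.seed(21)
  for (rep in 1:10) {
    g <- y_graph(runif(3, 10, 40),
                 soma_seg = sample(1:3, 3, replace = TRUE),
                 soma_arc = runif(3, 0, 10))
    p <- point_on_vessel(sample(1:3, 1), runif(1, 0, 10))
    best <- nearest_soma_distance(g, p)$distance
    for (i in seq_len(nrow(g$somata))) {
      expect_lte(best, arc_distance(g, p,
                                    point_on_vessel(g$somata$segment[i],
                                                    g$somata$arc_pos[i])) +
                   1e-9)
    }
  }
})

test_that("restriction to the named capillary excludes other capillaries", {
  g <- capillary_graph(
    list(cbind(c(0, 30), c(0, 0)), cbind(c(30, 60), c(0, 0)),
         rbind(c(30, 0), c(30, 10))),
    c("cap1", "cap1", "con1"),
    somata = data.frame(segment = c(2, 3), arc_pos = c(20, 5),
                        visible = TRUE))
  p <- point_on_vessel(1, 30)
  expect_equal(nearest_soma_distance(g, p, "capillary")$distance, 20)
  expect_equal(nearest_soma_distance(g, p, "component")$distance, 5)
})

test_that("intersoma distances cover adjacent pairs per capillary", {
  g <- straight_capillary(120, soma_arcs = c(0, 60, 120))
  expect_equal(sort(intersoma_distances(g)), c(60, 60))
  expect_equal(mean(intersoma_distances(g)), 60)
  g1 <- straight_capillary(60, soma_arcs = 30)
  expect_length(intersoma_distances(g1), 0)
  g2 <- capillary_graph(
    list(cbind(c(0, 100), c(0, 0)), cbind(c(0, 100), c(50, 50))),
    c("cap1", "cap2"),
    somata = data.frame(segment = c(1, 1, 2, 2),
                        arc_pos = c(0, 50, 10, 80), visible = TRUE))
  expect_equal(sort(intersoma_distances(g2)), c(50, 70))
  # straight horizontal capillaries: chord equals arc
  expect_equal(sort(intersoma_distances(g2, method = "euclidean")),
               c(50, 70))
})

test_that("graphs round-trip through the CSV/JSON schema", {
  g <- y_graph(c(20, 25, 30), soma_seg = c(1, 2), soma_arc = c(3, 7))
  g$blockages <- data.frame(segment = 3L, arc_pos = 12)
  dir <- withr::local_tempdir()
  write_capillary_graph(g, dir)
  g2 <- read_capillary_graph(dir)
  expect_equal(g2$seg_len, g$seg_len, tolerance = 1e-12)
  expect_equal(g2$capillary_ids, g$capillary_ids)
  expect_equal(g2$somata, g$somata)
  expect_equal(g2$blockages$arc_pos, 12)
  expect_equal(nearest_soma_distance(g2, point_on_vessel(3, 12))$distance,
               nearest_soma_distance(g, point_on_vessel(3, 12))$distance)
})

test_that("constructor rejects invalid geometry and annotations", {
  expect_error(capillary_graph(list(), "a"), "non-empty")
  expect_error(capillary_graph(list(cbind(c(0, 0), c(0, 0))), "a"),
               "positive length")
  expect_error(
    capillary_graph(list(cbind(c(0, 10), c(0, 0))), "a",
                    somata = data.frame(segment = 1, arc_pos = 11,
                                        visible = TRUE)),
    "outside its segment")
  expect_error(
    capillary_graph(list(cbind(c(0, 10), c(0, 0))), "a",
                    somata = data.frame(segment = 2, arc_pos = 1,
                                        visible = TRUE)),
    "does not exist")
})
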