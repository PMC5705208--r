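# Fixture builders and the brute-force discretization oracle used to verify
# the exact null-model computation.

with_seed_helper <- function(seed, expr) withr::with_seed(seed, expr)

derive_seed_helper <- function(...) periflow:::derive_seed(...)

straight_capillary <- function(L, soma_arcs = numeric(), visible = TRUE,
                               blockage_arcs = numeric()) {
  capillary_graph(
    list(cbind(x = c(0, L), y = c(0, 0))), "cap1",
    somata = if (length(soma_arcs))
      data.frame(segment = 1, arc_pos = soma_arcs,
                 visible = rep_len(visible, length(soma_arcs))),
    blockages = if (length(blockage_arcs))
      data.frame(segment = 1, arc_pos = blockage_arcs))
}

# three segments radiating from a shared node at the origin; segment arcs
# are measured outward from the junction
y_graph <- function(lens = c(20, 20, 20), soma_seg = integer(),
                    soma_arc = numeric()) {
  dirs <- list(c(1, 0), c(-1, 1) / sqrt(2), c(-1, -1) / sqrt(2))
  segs <- lapply(1:3, function(i) {
    rbind(c(0, 0), dirs[[i]] * lens[i])
  })
  capillary_graph(segs, rep("cap1", 3),
                  somata = if (length(soma_seg))
                    data.frame(segment = soma_seg, arc_pos = soma_arc,
                               visible = TRUE))
}

# Exact nearest-soma distance at arc positions s on one arm of a Y graph
# (or on a straight capillary when soma_seg is all 1 and n_arms == 1),
# enumerated from first principles: same-arm direct |s - a|, or out through
# the junction, s + a.
y_oracle_distance <- function(s, arm, soma_seg, soma_arc) {
  d <- rep(Inf, length(s))
  for (k in seq_along(soma_seg)) {
    d <- if (soma_seg[k] == arm) {
      pmin(d, abs(s - soma_arc[k]), s + soma_arc[k])
    } else {
      pmin(d, s + soma_arc[k])
    }
  }
  d
}

# Integrate the indicator {d <= x} over arc cells of width h from edge
# samples of d, assuming d is linear within each cell (exact when every
# kink of d lies on a cell edge).
oracle_cdf_from_edges <- function(d_edges, h, L, qs) {
  d0 <- utils::head(d_edges, -1)
  d1 <- utils::tail(d_edges, -1)
  lo <- pmin(d0, d1)
  rng <- pmax(abs(d1 - d0), 1e-15)
  vapply(qs, function(x) sum(pmin(pmax((x - lo) / rng, 0), 1)) * h / L, 0)
}

# query points where two CDFs should be compared: breakpoints and midpoints
cdf_query_points <- function(cdf) {
  b <- cdf$breakpoints
  sort(unique(c(b, (utils::head(b, -1) + utils::tail(b, -1)) / 2)))
}

# brute-force (0.01 um discretization) check of image_null_cdf on a random
# lattice geometry; returns the sup-norm discrepancy
null_cdf_vs_oracle <- function(branched, step = 0.01) {
  snap <- function(x) round(x / 0.02) * 0.02
  if (!branched) {
    L <- snap(runif(1, 20, 80))
    ns <- sample(1:3, 1)
    a <- snap(runif(ns, 0.1, L - 0.1))
    g <- straight_capillary(L, a)
    cdf <- image_null_cdf(g, "cap1")
    qs <- cdf_query_points(cdf)
    d <- y_oracle_distance(seq(0, L, by = step), 1, rep(1, ns), a)
    est <- oracle_cdf_from_edges(d, step, L, qs)
  } else {
    lens <- snap(runif(3, 10, 40))
    nsom <- sample(1:3, 1)
    sseg <- sample(1:3, nsom, replace = TRUE)
    sarc <- snap(runif(nsom, 0.1, lens[sseg] - 0.1))
    g <- y_graph(lens, sseg, sarc)
    cdf <- image_null_cdf(g, "cap1")
    qs <- cdf_query_points(cdf)
    L <- sum(lens)
    est <- rep(0, length(qs))
    for (arm in 1:3) {
      d <- y_oracle_distance(seq(0, lens[arm], by = step), arm, sseg, sarc)
      est <- est + oracle_cdf_from_edges(d, step, L, qs)
    }
  }
  max(abs(cdf_prob(cdf, qs) - est))
}
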