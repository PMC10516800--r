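# replays a known edge count through the density machinery
make_count_edges <- function(registry, n_cp, n_cp_th) {
  cp <- registry$roi_id[registry$structure == "CP"]
  th <- registry$roi_id[registry$structure == "TH"]
  within <- t(combn(cp, 2))[seq_len(n_cp), , drop = FALSE]
  cross <- expand.grid(cp = cp, th = th, stringsAsFactors = FALSE)[seq_len(n_cp_th), ]
  edge_set(c(within[, 1], cross$cp), c(within[, 2], cross$th), sign = "+")
}

test_that("connectivity density reproduces the published worked examples", {
  reg <- default_registry()
  edges <- make_count_edges(reg, 151, 10)
  expect_equal(round(connectivity_density(edges, reg, "CP", "CP", "+"), 2), 7.04)
  expect_equal(round(connectivity_density(edges, reg, "CP", "TH", "+"), 2), 0.72)
  expect_equal(connectivity_density(edges, reg, "CP", "CP", "-"), 0)
  empty <- edge_set(character(0), character(0))
  expect_equal(connectivity_density(empty, reg, "CP", "TH", "+"), 0)
})

test_that("the density table agrees cell-by-cell with single-pair densities", {
  reg <- default_registry()
  edges <- make_count_edges(reg, 40, 7)
  rep <- density_table(edges, reg)
  expect_setequal(unique(c(rep$structure_a, rep$structure_b)), CBT_STRUCTURES)
  for (k in seq_len(nrow(rep))) {
    expect_equal(rep$positive_density[k],
                 connectivity_density(edges, reg, rep$structure_a[k],
                                      rep$structure_b[k], "+"))
    expect_equal(rep$pair_count[k],
                 pair_count(reg, rep$structure_a[k], rep$structure_b[k]))
  }
  # edge counts over all structure pairs partition the edge set
  expect_equal(sum(rep$positive_count) + sum(rep$negative_count), nrow(edges))
  m <- density_matrix(rep, "+")
  expect_true(isSymmetric(m))
  expect_equal(rownames(m), CBT_STRUCTURES)
})

test_that("a saturated positive edge set gives 100% density everywhere", {
  reg <- toy_registry(c(CP = 4, TH = 3))
  pairs <- t(combn(reg$roi_id, 2))
  edges <- edge_set(pairs[, 1], pairs[, 2], sign = "+")
  rep <- density_table(edges, reg)
  expect_true(all(rep$positive_density == 100))
  expect_true(all(rep$negative_density == 0))
})

test_that("node degrees obey the handshake lemma", {
  reg <- toy_registry(c(CP = 3))
  tri <- edge_set(c("CP_01", "CP_01", "CP_02"), c("CP_02", "CP_03", "CP_03"))
  deg <- node_degrees(connectivity_graph(tri, reg))
  expect_equal(deg$degree, c(2L, 2L, 2L))

  star_reg <- toy_registry(c(CP = 6))
  star <- edge_set(rep("CP_01", 5), sprintf("CP_%02d", 2:6))
  sdeg <- node_degrees(connectivity_graph(star, star_reg))
  expect_equal(sdeg$degree, c(5L, rep(1L, 5)))

  for (s in 1:5) {
    set.seed(s)
    regn <- toy_registry(c(CP = 8, TH = 4))
    pairs <- t(combn(regn$roi_id, 2))
    keep <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    es <- edge_set(keep[, 1], keep[, 2],
                   sign = sample(c("+", "-"), nrow(keep), replace = TRUE))
    d <- node_degrees(connectivity_graph(es, regn))
    expect_equal(sum(d$degree), 2 * nrow(es))
  }
})

test_that("hub flagging takes the top ceiling(fraction * N) with registry-order ties", {
  reg <- default_registry()
  es <- make_count_edges(reg, 100, 5)
  rep <- identify_hubs(node_degrees(connectivity_graph(es, reg)))
  expect_equal(sum(rep$hub_flag), 18)   # ceiling(0.1 * 176)

  flat <- data.frame(roi_id = sprintf("r%02d", 1:20), structure = "CP",
                     degree = rep(3L, 20))
  fr <- identify_hubs(structure(flat, class = c("degree_report", "data.frame")))
  expect_equal(which(fr$hub_flag), 1:2)  # all tied: first ceiling(0.1*20) in order

  distinct <- data.frame(roi_id = sprintf("r%02d", 1:10), structure = "CP",
                         degree = 10:1)
  dr <- identify_hubs(structure(distinct, class = c("degree_report", "data.frame")))
  expect_equal(which(dr$hub_flag), 1L)
  expect_equal(dr$rank, 1:10)
})

test_that("degree changes rank gains first and negate under swap", {
  reg <- toy_registry(c(CP = 5))
  g1 <- connectivity_graph(edge_set("CP_01", "CP_02"), reg)
  g2 <- connectivity_graph(edge_set(c("CP_01", "CP_01", "CP_01", "CP_03"),
                                    c("CP_02", "CP_04", "CP_05", "CP_04")), reg)
  d1 <- node_degrees(g1); d2 <- node_degrees(g2)
  dc <- degree_change(d1, d2)
  expect_equal(dc$roi_id[1], "CP_01")
  expect_equal(dc$delta[1], 2L)
  expect_equal(sum(dc$delta), 2 * (4 - 1))   # handshake on the difference
  back <- degree_change(d2, d1)
  expect_equal(sort(back$delta), sort(-dc$delta))
  expect_equal(degree_change(d1, d1)$delta, rep(0L, 5))
  d3 <- d1; d3$roi_id[1] <- "other"
  expect_error(degree_change(d1, d3), "different node sets")
})

test_that("the energised layout separates cliques and is seed-deterministic", {
  reg <- toy_registry(c(CP = 4, TH = 4))
  cp_pairs <- t(combn(reg$roi_id[1:4], 2))
  th_pairs <- t(combn(reg$roi_id[5:8], 2))
  es <- edge_set(c(cp_pairs[, 1], th_pairs[, 1]), c(cp_pairs[, 2], th_pairs[, 2]))
  g <- connectivity_graph(es, reg)
  c1 <- layout_network(g, seed = 3)
  c2 <- layout_network(g, seed = 3)
  expect_identical(c1, c2)
  dmat <- as.matrix(dist(c1))
  intra <- c(dmat[1:4, 1:4][upper.tri(diag(4))], dmat[5:8, 5:8][upper.tri(diag(4))])
  inter <- dmat[1:4, 5:8]
  expect_lt(mean(intra), mean(inter))

  single <- connectivity_graph(edge_set(character(0), character(0)),
                               toy_registry(c(CP = 1)))
  expect_equal(unname(layout_network(single, 1)), matrix(0, 1, 2))

  # isolated nodes sit on a peripheral ring outside the connected layout
  reg2 <- toy_registry(c(CP = 4, TH = 2))
  es2 <- edge_set(cp_pairs[, 1], cp_pairs[, 2])
  co <- layout_network(connectivity_graph(es2, reg2), seed = 1)
  rad <- sqrt(rowSums(co^2))
  expect_true(all(rad[5:6] >= max(rad[1:4])))
})

test_that("GraphML export round-trips nodes, signs and hub flags", {
  reg <- toy_registry(c(CP = 4, TH = 2))
  es <- edge_set(c("CP_01", "CP_02"), c("CP_03", "TH_01"), sign = c("+", "-"))
  g <- connectivity_graph(es, reg)
  f <- tempfile(fileext = ".graphml")
  write_graphml(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 6)
  expect_equal(igraph::ecount(back), 2)
  expect_setequal(igraph::E(back)$sign, c("+", "-"))
  expect_equal(sum(igraph::V(back)$hub), 1)  # ceiling(0.1 * 6)
})
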