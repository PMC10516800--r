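test_that("pearson_matrix reproduces hand-checked coefficients", {
  x <- c(1, 2, 3, 4, 5)
  tab <- toy_table(cbind(x, 2 * x, rev(x), c(1, 2, 3, 4, 6), x + rnorm(5, 0, 10)))
  res <- pearson_matrix(tab)
  expect_equal(res$r[1, 2], 1)
  expect_equal(res$r[1, 3], -1)
  expect_equal(res$r[1, 4], 0.986394, tolerance = 1e-6)  # product-moment oracle
  expect_equal(res$n, 5)
  expect_true(isSymmetric(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 5))
  expect_true(all(is.na(diag(res$p))))
})

test_that("correlation p-values agree with the standard t-based test", {
  set.seed(11)
  tab <- toy_table(matrix(rnorm(60, 100, 5), 10, 6))
  res <- pearson_matrix(tab)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      ct <- cor.test(tab$values[, i], tab$values[, j])
      expect_equal(res$p[i, j], unname(ct$p.value), tolerance = 1e-12)
    }
  }
})

test_that("pearson_matrix is invariant to positive affine maps and flips under negative slope", {
  set.seed(5)
  tab <- toy_table(matrix(rnorm(40, 100, 5), 8, 5))
  r0 <- pearson_matrix(tab)$r
  tab2 <- tab; tab2$values[, 2] <- 3 * tab$values[, 2] + 17
  expect_equal(pearson_matrix(tab2)$r, r0, tolerance = 1e-12)
  tab3 <- tab; tab3$values[, 2] <- -2 * tab$values[, 2] + 5
  r3 <- pearson_matrix(tab3)$r
  expect_equal(r3[2, -2], -r0[2, -2], tolerance = 1e-12)
  expect_equal(r3[-2, -2], r0[-2, -2], tolerance = 1e-12)
})

test_that("the Fisher r-to-z transform is the odd, monotone atanh map", {
  expect_equal(r_to_z(0), 0)
  expect_equal(r_to_z(0.5), 0.549306, tolerance = 1e-6)  # high-precision log oracle
  rs <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(r_to_z(-rs), -r_to_z(rs))
  expect_true(all(diff(r_to_z(rs)) > 0))
  expect_error(r_to_z(1), "defined only")
  expect_error(r_to_z(-1.2), "defined only")
})

test_that("a perfectly coupled ROI pair survives the jackknife with positive sign", {
  set.seed(2)
  base <- rnorm(10, 100, 5)
  vals <- cbind(base, 2.5 * base + 40, matrix(rnorm(30, 100, 5), 10, 3))
  es <- reliable_edges_jackknife(toy_table(vals))
  expect_true(any(es$roi_i == "R_01" & es$roi_j == "R_02"))
  hit <- es[es$roi_i == "R_01" & es$roi_j == "R_02", ]
  expect_equal(hit$sign, "+")
  expect_equal(hit$r_full, 1)
})

test_that("jackknife edge selection matches an explicit leave-one-out loop", {
  for (s in 1:6) {
    n <- 5 + (s %% 4)   # n in 5..8
    R <- diag(8)
    R[1, 2] <- R[2, 1] <- 0.9
    R[3, 4] <- R[4, 3] <- -0.85
    vals <- draw_mvn(n, R, seed = 100 + s)
    tab <- toy_table(vals)
    got <- edge_keys(reliable_edges_jackknife(tab), tab$roi_ids)
    want <- oracle_keys(bf_reliable_edges(vals))
    expect_identical(got, want)
  }
})

test_that("jackknife inclusion is monotone in alpha", {
  tab <- toy_table(draw_mvn(8, diag(6), seed = 9))
  ids <- tab$roi_ids
  previous <- character(0)
  for (a in c(1e-12, 0.01, 0.05, 0.5, 1.0)) {
    keys <- edge_keys(reliable_edges_jackknife(tab, alpha = a), ids)
    expect_true(all(previous %in% keys))
    previous <- keys
  }
  expect_equal(length(edge_keys(reliable_edges_jackknife(tab, alpha = 1e-12), ids)), 0)
  # at alpha = 1 only the sign-consistency clause remains binding: included
  # edges are exactly the pairs whose leave-one-out signs never flip
  n <- nrow(tab$values)
  consistent <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    signs <- vapply(1:n, function(k) sign(cor(tab$values[-k, i], tab$values[-k, j])), numeric(1))
    if (length(unique(signs)) == 1) consistent <- c(consistent, paste(i, j, sep = "-"))
  }
  expect_identical(edge_keys(reliable_edges_jackknife(tab, alpha = 1.0), ids),
                   sort(consistent))
})

test_that("included edges carry consistent per-iteration diagnostics", {
  R <- diag(6); R[1, 2] <- R[2, 1] <- 0.95; R[3, 4] <- R[4, 3] <- 0.9
  tab <- toy_table(draw_mvn(10, R, seed = 4))
  es <- reliable_edges_jackknife(tab, alpha = 0.05)
  diag_df <- attr(es, "diagnostics")
  expect_equal(nrow(diag_df), nrow(es))
  expect_true(all(diag_df$p_max < 0.05))
  expect_true(all(diag_df$r_abs_min > 0))
})

test_that("strict mode additionally requires full-sample significance", {
  set.seed(31)
  tab <- toy_table(draw_mvn(10, diag(10), seed = 31))
  es <- reliable_edges_jackknife(tab, alpha = 0.9)
  es_strict <- reliable_edges_jackknife(tab, alpha = 0.9, strict_full_sample = TRUE)
  expect_lte(nrow(es_strict), nrow(es))
  full_p <- pearson_matrix(tab)$p
  ids <- tab$roi_ids
  for (k in seq_len(nrow(es_strict))) {
    expect_lt(full_p[match(es_strict$roi_i[k], ids), match(es_strict$roi_j[k], ids)], 0.9)
  }
})
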