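# In-code fixtures and independent brute-force oracles used across tests.

# small registry with the given per-structure ROI counts (named vector)
toy_registry <- function(counts) {
  rows <- do.call(rbind, lapply(names(counts), function(s) {
    k <- counts[[s]]
    data.frame(roi_id = sprintf("%s_%02d", s, seq_len(k)),
               structure = s, subdivision = s,
               domain_label = sprintf("%s.%d", s, seq_len(k)),
               bregma_mm = seq(1, by = -0.1, length.out = k),
               stringsAsFactors = FALSE)
  }))
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  load_registry(path)
}

# uptake table straight from a matrix, with generated ids
toy_table <- function(values, group = "g") {
  colnames(values) <- sprintf("R_%02d", seq_len(ncol(values)))
  uptake_table(values, subject_ids = sprintf("s%02d", seq_len(nrow(values))),
               roi_ids = colnames(values), group_name = group)
}

# draw an n x p matrix with a given correlation matrix (independent of the
# package generator: base rnorm + chol)
draw_mvn <- function(n, R, mean = 100, sd = 5, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  z <- matrix(rnorm(n * p), n, p) %*% chol(R)
  mean + sd * z
}

# --- independent oracles -------------------------------------------------

# leave-one-out reliability by explicit looping over cor.test
bf_reliable_edges <- function(values, alpha = 0.05) {
  n <- nrow(values); p <- ncol(values)
  out <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      signs <- numeric(n); ok <- TRUE
      for (k in seq_len(n)) {
        ct <- stats::cor.test(values[-k, i], values[-k, j])
        if (!(ct$p.value < alpha)) { ok <- FALSE; break }
        signs[k] <- sign(unname(ct$estimate))
      }
      if (ok && length(unique(signs)) == 1) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# explicit 2n-loop double jackknife on the Fisher Z statistic
bf_reliable_diffs <- function(v1, v2, alpha = 0.05) {
  n1 <- nrow(v1); n2 <- nrow(v2); p <- ncol(v1)
  zstat <- function(x1, y1, x2, y2, m1, m2) {
    lim <- 1 - 1e-15
    r1 <- min(max(cor(x1, y1), -lim), lim)
    r2 <- min(max(cor(x2, y2), -lim), lim)
    (atanh(r1) - atanh(r2)) / sqrt(1 / (m1 - 3) + 1 / (m2 - 3))
  }
  out <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      zs <- numeric(0); ok <- TRUE
      for (k in seq_len(n1)) {
        Z <- zstat(v1[-k, i], v1[-k, j], v2[, i], v2[, j], n1 - 1, n2)
        if (!(2 * pnorm(-abs(Z)) < alpha)) { ok <- FALSE; break }
        zs <- c(zs, sign(Z))
      }
      if (ok) for (k in seq_len(n2)) {
        Z <- zstat(v1[, i], v1[, j], v2[-k, i], v2[-k, j], n1, n2 - 1)
        if (!(2 * pnorm(-abs(Z)) < alpha)) { ok <- FALSE; break }
        zs <- c(zs, sign(Z))
      }
      if (ok && length(unique(zs)) == 1) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# canonical "i-j" keys for comparing edge sets against oracle index pairs
edge_keys <- function(edges, roi_ids) {
  if (nrow(edges) == 0) return(character(0))
  i <- match(edges$roi_i, roi_ids); j <- match(edges$roi_j, roi_ids)
  sort(paste(pmin(i, j), pmax(i, j), sep = "-"))
}

oracle_keys <- function(idx) {
  if (nrow(idx) == 0) return(character(0))
  sort(paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]), sep = "-"))
}
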