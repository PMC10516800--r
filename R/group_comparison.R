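#' Fisher Z-test for the difference of two independent correlations
#'
#' \deqn{Z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'                {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' A positive Z means \code{r1} exceeds \code{r2}. Under the null of equal
#' population correlations Z is approximately standard normal, giving the
#' two-sided p-value \code{2 * (1 - pnorm(|Z|))}. Coefficients at exactly
#' |r| = 1 are clamped to 1 - 1e-15 so the statistic stays finite (two
#' perfect correlations of equal sign still give Z = 0).
#'
#' @param r1,r2 Correlation coefficients (vectors or matrices of matching
#'   shape), in [-1, 1].
#' @param n1,n2 Group sample sizes, each at least 4.
#' @return List with \code{Z} and two-sided \code{p}, shaped like the input.
#' @export
fisher_z <- function(r1, r2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) {
    stop("fisher_z requires n1 > 3 and n2 > 3", call. = FALSE)
  }
  lim <- 1 - 1e-15
  z1 <- atanh(pmin(pmax(r1, -lim), lim))
  z2 <- atanh(pmin(pmax(r2, -lim), lim))
  Z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p = 2 * pnorm(abs(Z), lower.tail = FALSE))
}

#' Between-group edge differences with double-jackknife reliability
#'
#' Tests every ROI pair for a group difference in correlation with the
#' Fisher Z statistic, protected by a 2n-iteration jackknife: one subject
#' is dropped sequentially from either group (the other group kept at full
#' n) and the Z matrix recomputed, so each iteration compares n and n - 1
#' subjects. A difference is reliable only if it is significant
#' (p < \code{alpha}) with a consistent Z sign in all 2n iterations. Signs
#' follow the full-sample Z: positive means the first group's correlation
#' is larger.
#'
#' @param tab1,tab2 \code{uptake_table}s for the two groups with identical
#'   ROI ordering and at least 5 subjects each. The study design has equal
#'   group sizes; unequal sizes are supported (with a warning) by running
#'   n1 + n2 drop-one iterations.
#' @param alpha Per-iteration significance level (default 0.05).
#' @param strict_full_sample If \code{TRUE}, additionally require full-sample
#'   significance.
#' @return A \code{group_z_result}: list with full-sample \code{Z} and
#'   \code{p} matrices, group sizes \code{n1}, \code{n2}, the boolean
#'   \code{reliable_mask}, and \code{edges}, an \code{edge_set} data frame
#'   (\code{roi_i}, \code{roi_j}, \code{sign}, \code{Z_full}).
#' @export
reliable_differences_double_jackknife <- function(tab1, tab2, alpha = 0.05,
                                                  strict_full_sample = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  if (!identical(tab1$roi_ids, tab2$roi_ids)) {
    stop("the two groups must share the same ROI set and order", call. = FALSE)
  }
  n1 <- nrow(tab1$values); n2 <- nrow(tab2$values)
  if (n1 < 5 || n2 < 5) stop("double jackknife requires at least 5 subjects per group", call. = FALSE)
  if (n1 != n2) {
    warning(sprintf("unequal group sizes (%d vs %d); running %d drop-one iterations",
                    n1, n2, n1 + n2))
  }
  r1 <- cor(tab1$values); r2 <- cor(tab2$values)
  full <- fisher_z(r1, r2, n1, n2)
  p_rois <- length(tab1$roi_ids)
  all_sig <- matrix(TRUE, p_rois, p_rois)
  sign_ref <- NULL
  sign_ok <- matrix(TRUE, p_rois, p_rois)
  drop_iteration <- function(vals1, vals2, nn1, nn2) {
    for (m in list(vals1, vals2)) {
      cv <- apply(m, 2, var)
      if (any(cv == 0)) {
        stop(sprintf("degenerate jackknife iteration: constant ROI column(s) %s",
                     paste(colnames(m)[cv == 0], collapse = ", ")), call. = FALSE)
      }
    }
    fisher_z(cor(vals1), cor(vals2), nn1, nn2)
  }
  step <- function(fz) {
    all_sig <<- all_sig & (fz$p < alpha)
    if (is.null(sign_ref)) sign_ref <<- sign(fz$Z) else sign_ok <<- sign_ok & (sign(fz$Z) == sign_ref)
  }
  for (k in seq_len(n1)) {
    step(drop_iteration(tab1$values[-k, , drop = FALSE], tab2$values, n1 - 1, n2))
  }
  for (k in seq_len(n2)) {
    step(drop_iteration(tab1$values, tab2$values[-k, , drop = FALSE], n1, n2 - 1))
  }
  keep <- all_sig & sign_ok
  if (strict_full_sample) keep <- keep & (full$p < alpha)
  diag(keep) <- FALSE
  idx <- edge_upper_indices(p_rois)
  sel <- idx[keep[idx], , drop = FALSE]
  rois <- tab1$roi_ids
  Z_full <- full$Z[sel]
  edges <- data.frame(roi_i = rois[sel[, 1]], roi_j = rois[sel[, 2]],
                      sign = ifelse(Z_full >= 0, "+", "-"),
                      Z_full = Z_full, stringsAsFactors = FALSE)
  edges <- new_edge_set(edges, provenance = "group_difference", alpha = alpha)
  Zm <- full$Z; pm <- full$p
  dimnames(Zm) <- dimnames(pm) <- list(rois, rois)
  diag(Zm) <- NA_real_; diag(pm) <- NA_real_
  keep_named <- keep; dimnames(keep_named) <- list(rois, rois)
  structure(list(Z = Zm, p = pm, n1 = n1, n2 = n2,
                 reliable_mask = keep_named, edges = edges,
                 alpha = alpha,
                 groups = c(tab1$group_name, tab2$group_name)),
            class = "group_z_result")
}

#' @export
print.group_z_result <- function(x, ...) {
  cat(sprintf("group_z_result %s vs %s: %d ROIs, n = %d/%d, %d reliable difference(s) at alpha = %g\n",
              x$groups[1], x$groups[2], nrow(x$Z), x$n1, x$n2, nrow(x$edges), x$alpha))
  invisible(x)
}
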