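#' Specify a block-structured target correlation for synthetic uptake data
#'
#' Encodes the cross-subject covariance the generator samples from: ROIs in
#' the same structure share a common within-block correlation, selected ROI
#' pairs carry planted correlations (overriding the block value), and all
#' remaining off-block pairs are uncorrelated. This mirrors the statistical
#' structure a cross-subject connectivity analysis assumes — coherent
#' covariation of regional uptake within functional structures.
#'
#' @param roi_count Number of ROIs.
#' @param block_assignment Character vector of length \code{roi_count}
#'   assigning each ROI to a structure block (typically
#'   \code{registry$structure}).
#' @param within_block_r Either a single correlation in (-1, 1) applied to
#'   every block, or a named vector with one entry per structure.
#' @param planted_edges Optional data frame with columns \code{i}, \code{j}
#'   (ROI indices or ids) and \code{r}, each \code{r} in (-1, 1).
#' @param baseline_mean Positive mean uptake level (arbitrary optical-density
#'   units; default 100 matches the global-scaling target).
#' @param noise_sd Positive between-subject standard deviation.
#' @return A \code{covariance_spec} object.
#' @export
covariance_spec <- function(roi_count, block_assignment,
                            within_block_r = 0, planted_edges = NULL,
                            baseline_mean = 100, noise_sd = 5) {
  stopifnot(roi_count >= 1, length(block_assignment) == roi_count,
            baseline_mean > 0, noise_sd > 0)
  if (any(abs(within_block_r) >= 1)) {
    stop("within_block_r must lie in the open interval (-1, 1)", call. = FALSE)
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("i", "j", "r") %in% names(planted_edges)))
    if (any(abs(planted_edges$r) >= 1)) {
      stop("planted edge correlations must lie in (-1, 1)", call. = FALSE)
    }
    if (any(planted_edges$i == planted_edges$j)) {
      stop("planted edges must join two distinct ROIs", call. = FALSE)
    }
  }
  structure(list(roi_count = roi_count,
                 block_assignment = as.character(block_assignment),
                 within_block_r = within_block_r,
                 planted_edges = planted_edges,
                 baseline_mean = baseline_mean,
                 noise_sd = noise_sd),
            class = "covariance_spec")
}

#' Build the target correlation matrix of a covariance spec
#'
#' Assembles the block/planted correlation matrix, then repairs it to the
#' nearest positive semi-definite matrix by clipping negative eigenvalues to
#' zero and re-normalising to unit diagonal. The repair magnitude (maximum
#' absolute entry change) is recorded in the \code{"psd_repair"} attribute;
#' a repair larger than \code{tol} means the requested correlations are
#' mutually infeasible and is an error rather than a silent distortion.
#'
#' @param spec A \code{covariance_spec}.
#' @param tol Maximum tolerated entry change during PSD repair (default 0.05).
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   \code{"psd_repair"} (the max absolute entry change; 0 when no repair
#'   was needed).
#' @export
build_correlation_matrix <- function(spec, tol = 0.05) {
  p <- spec$roi_count
  blocks <- spec$block_assignment
  rb <- spec$within_block_r
  if (length(rb) == 1 && is.null(names(rb))) rb <- setNames(rep(rb, length(unique(blocks))), unique(blocks))
  R <- matrix(0, p, p)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    r <- if (b %in% names(rb)) unname(rb[b]) else 0
    R[idx, idx] <- r
  }
  if (!is.null(spec$planted_edges)) {
    pe <- spec$planted_edges
    ii <- resolve_roi_index(pe$i, p)
    jj <- resolve_roi_index(pe$j, p)
    for (k in seq_along(ii)) {
      R[ii[k], jj[k]] <- pe$r[k]
      R[jj[k], ii[k]] <- pe$r[k]
    }
  }
  diag(R) <- 1
  e <- eigen(R, symmetric = TRUE)
  repair <- 0
  if (min(e$values) < 0) {
    vals <- pmax(e$values, 0)
    R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    diag(R2) <- 1
    R2 <- (R2 + t(R2)) / 2
    repair <- max(abs(R2 - R))
    if (repair > tol) {
      stop(sprintf(paste0("requested correlations are infeasible: PSD repair ",
                          "changed an entry by %.4f (> tol %.4f)"), repair, tol),
           call. = FALSE)
    }
    R <- R2
  }
  attr(R, "psd_repair") <- repair
  R
}

resolve_roi_index <- function(x, p, roi_ids = NULL) {
  if (is.numeric(x)) {
    stopifnot(all(x >= 1 & x <= p))
    return(as.integer(x))
  }
  if (is.null(roi_ids)) stop("character ROI references need roi ids in context", call. = FALSE)
  idx <- match(x, roi_ids)
  if (anyNA(idx)) stop(sprintf("unknown ROI id(s): %s", paste(x[is.na(idx)], collapse = ", ")), call. = FALSE)
  idx
}

#' Specify a synthetic subject group
#'
#' @param name Group label (e.g. "control", "exercise").
#' @param covariance A \code{covariance_spec}.
#' @param n_subjects Subjects per group; the study design is 10. Must be at
#'   least 4: the Fisher Z denominator needs n - 3 > 0 and each jackknife
#'   iteration drops one subject.
#' @param seed Integer seed driving this group's sampling stream.
#' @return A \code{group_spec} object.
#' @export
group_spec <- function(name, covariance, n_subjects = 10, seed = 1) {
  stopifnot(inherits(covariance, "covariance_spec"))
  if (n_subjects < 4) {
    stop("n_subjects must be at least 4 (jackknife and Fisher Z requirements)",
         call. = FALSE)
  }
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 covariance = covariance, seed = as.integer(seed)),
            class = "group_spec")
}

#' Sample a group uptake table from its spec
#'
#' Draws \code{n_subjects} multivariate-normal subject vectors with the
#' spec's target correlation matrix, scaled by \code{noise_sd} and shifted
#' by \code{baseline_mean}. Sampling is fully determined by the spec's seed.
#' In the measure-zero event of a degenerate draw (a zero-variance column),
#' the draw is rejected and resampled with the seed incremented, with a
#' message.
#'
#' @param spec A \code{group_spec}.
#' @param registry \code{roi_registry} supplying ROI ids and order; its
#'   length must equal the spec's \code{roi_count}.
#' @return An \code{uptake_table}.
#' @export
generate_group <- function(spec, registry) {
  p <- spec$covariance$roi_count
  if (nrow(registry) != p) {
    stop(sprintf("registry has %d ROIs but spec expects %d", nrow(registry), p),
         call. = FALSE)
  }
  R <- build_correlation_matrix(spec$covariance)
  Sigma <- spec$covariance$noise_sd^2 * R
  mu <- rep(spec$covariance$baseline_mean, p)
  seed <- spec$seed
  for (attempt in 1:10) {
    set.seed(seed)
    vals <- MASS::mvrnorm(spec$n_subjects, mu = mu, Sigma = Sigma)
    if (all(apply(vals, 2, var) > 0)) break
    message(sprintf("degenerate draw for group '%s' (seed %d); resampling with seed %d",
                    spec$name, seed, seed + 1))
    seed <- seed + 1
  }
  uptake_table(vals,
               subject_ids = sprintf("%s_s%02d", spec$name, seq_len(spec$n_subjects)),
               roi_ids = registry$roi_id, group_name = spec$name)
}

#' Derive a matched pair of group specs with planted edge differences
#'
#' Starting from a control-group spec, returns control and treatment specs
#' whose target correlation matrices differ only at the listed ROI pairs —
#' the ground-truth effect the double-jackknife Fisher Z comparison should
#' detect.
#'
#' @param spec_control A \code{group_spec} for the control group.
#' @param edges Data frame with columns \code{i}, \code{j} (ROI indices),
#'   \code{r_control}, \code{r_exercise}, all correlations in (-1, 1).
#'   May be empty, giving two groups with identical covariance.
#' @param name_exercise Label for the derived group.
#' @param seed_exercise Seed for the derived group's sampling stream
#'   (defaults to the control seed + 1 so the two groups are independent).
#' @return List with elements \code{control} and \code{exercise}, both
#'   \code{group_spec}s.
#' @export
plant_group_difference <- function(spec_control, edges,
                                   name_exercise = "exercise",
                                   seed_exercise = spec_control$seed + 1L) {
  edges <- as.data.frame(edges)
  cov_c <- spec_control$covariance
  if (nrow(edges) > 0) {
    stopifnot(all(c("i", "j", "r_control", "r_exercise") %in% names(edges)))
    if (any(abs(edges$r_control) >= 1) || any(abs(edges$r_exercise) >= 1)) {
      stop("edge correlations must lie in the open interval (-1, 1)", call. = FALSE)
    }
    cov_c$planted_edges <- rbind(cov_c$planted_edges,
                                 data.frame(i = edges$i, j = edges$j, r = edges$r_control))
  }
  cov_e <- cov_c
  if (nrow(edges) > 0) {
    ne <- nrow(edges)
    n_all <- nrow(cov_e$planted_edges)
    cov_e$planted_edges$r[(n_all - ne + 1):n_all] <- edges$r_exercise
  }
  # both target matrices must be feasible before any sampling happens
  build_correlation_matrix(cov_c)
  build_correlation_matrix(cov_e)
  list(control = group_spec(spec_control$name, cov_c,
                            n_subjects = spec_control$n_subjects,
                            seed = spec_control$seed),
       exercise = group_spec(name_exercise, cov_e,
                             n_subjects = spec_control$n_subjects,
                             seed = seed_exercise))
}
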