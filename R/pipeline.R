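#' Assemble a pipeline configuration
#'
#' @param registry Path to the registry CSV (default: shipped 176-ROI file).
#' @param group_files Named character vector of length 2: paths to the two
#'   group uptake CSVs; names are the group labels.
#' @param alpha Significance level used throughout (default 0.05).
#' @param hub_fraction Top-degree fraction flagged as hubs (default 0.10).
#' @param target_mean Global-scaling target for subject means (default 100).
#' @param layout_seed Seed for the graph layout.
#' @param out_dir Output directory (created if needed).
#' @param strict_full_sample Require full-sample significance on top of the
#'   jackknife criteria.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(group_files, out_dir,
                            registry = default_registry_path(),
                            alpha = 0.05, hub_fraction = 0.10,
                            target_mean = 100, layout_seed = 1,
                            strict_full_sample = FALSE) {
  stopifnot(length(group_files) == 2, alpha > 0, alpha < 1,
            hub_fraction > 0, hub_fraction < 1, target_mean > 0)
  if (is.null(names(group_files)) || any(names(group_files) == "")) {
    names(group_files) <- sprintf("group%d", 1:2)
  }
  structure(list(registry = registry, group_files = group_files,
                 alpha = alpha, hub_fraction = hub_fraction,
                 target_mean = target_mean, layout_seed = layout_seed,
                 out_dir = out_dir, strict_full_sample = strict_full_sample),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching \code{\link{pipeline_config}}
#'   arguments; \code{group_files} is a mapping of group name to CSV path.
#' @return A \code{pipeline_config}.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gf <- unlist(y$group_files)
  do.call(pipeline_config, c(list(group_files = gf),
                             y[setdiff(names(y), "group_files")]))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full connectivity pipeline
#'
#' End-to-end reproduction of the analysis shape: two group uptake tables
#' in; per-group correlation matrices (r/z/p), jackknife-reliable edge
#' sets, the double-jackknife group-difference Z matrix, signed
#' connectivity-density tables, graphs with degrees, hubs and Kamada-Kawai
#' coordinates, and a ranked degree-change table out — all written under
#' \code{config$out_dir}, with a JSON manifest summarising counts.
#' Deterministic for fixed inputs and seeds.
#'
#' @param config A \code{pipeline_config}.
#' @return The manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- stage("registry", load_registry(config$registry))
  gnames <- names(config$group_files)
  tabs <- list()
  for (g in gnames) {
    tabs[[g]] <- stage(paste0("read:", g), {
      tab <- read_uptake(config$group_files[[g]], registry, group_name = g)
      global_scale(tab, config$target_mean)
    })
  }
  edge_sets <- list(); density_reports <- list(); degree_reports <- list()
  out <- function(...) file.path(config$out_dir, sprintf(...))
  for (g in gnames) {
    res <- stage(paste0("correlate:", g), pearson_matrix(tabs[[g]]))
    write_matrix_csv(res$r, out("%s_r.csv", g))
    write_matrix_csv(res$z, out("%s_z.csv", g))
    write_matrix_csv(res$p, out("%s_p.csv", g))
    es <- stage(paste0("jackknife:", g),
                reliable_edges_jackknife(tabs[[g]], config$alpha,
                                         config$strict_full_sample))
    edge_sets[[g]] <- es
    write_edge_set(es, out("%s_edges.csv", g))
    density_reports[[g]] <- density_table(es, registry)
    write.csv(density_reports[[g]], out("%s_density.csv", g), row.names = FALSE)
    graph <- connectivity_graph(es, registry)
    deg <- identify_hubs(node_degrees(graph), config$hub_fraction)
    degree_reports[[g]] <- deg
    write.csv(deg, out("%s_degrees.csv", g), row.names = FALSE)
    write_graphml(graph, out("%s_network.graphml", g), config$hub_fraction)
    coords <- layout_network(graph, config$layout_seed)
    write.csv(data.frame(roi_id = rownames(coords), coords),
              out("%s_layout.csv", g), row.names = FALSE)
  }
  diff <- stage("group_difference",
                reliable_differences_double_jackknife(tabs[[gnames[1]]], tabs[[gnames[2]]],
                                                      config$alpha,
                                                      config$strict_full_sample))
  write_matrix_csv(diff$Z, out("difference_Z.csv"))
  write_matrix_csv(diff$p, out("difference_p.csv"))
  write_edge_set(diff$edges, out("difference_edges.csv"))
  dchange <- degree_change(degree_reports[[gnames[1]]], degree_reports[[gnames[2]]])
  write.csv(dchange, out("degree_change.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metaconn")),
    config = unclass(config),
    n_rois = nrow(registry),
    groups = lapply(setNames(gnames, gnames), function(g) list(
      n_subjects = nrow(tabs[[g]]$values),
      n_edges = nrow(edge_sets[[g]]),
      n_positive = sum(edge_sets[[g]]$sign == "+"),
      n_negative = sum(edge_sets[[g]]$sign == "-"),
      n_hubs = sum(degree_reports[[g]]$hub_flag),
      hubs = degree_reports[[g]]$roi_id[degree_reports[[g]]$hub_flag])),
    n_reliable_differences = nrow(diff$edges))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Synthetic two-group study emulating the exercise design
#'
#' Builds matched control and exercise group specs over the shipped 176-ROI
#' registry: 10 subjects per group, block-correlated uptake within each
#' structure, and a small set of planted between-group edge differences
#' (exercise-gained caudoputamen-motor couplings and control-only
#' thalamus-prefrontal couplings) that provide ground truth for the
#' group-comparison stage. The planted endpoint ROIs are decoupled from
#' their structure's common block correlation — a strong cross-structure
#' coupling is geometrically incompatible with simultaneous strong
#' within-block coupling, and the decoupling models a region rewired away
#' from its home structure.
#'
#' @param seed Integer seed; the two groups draw from independent streams
#'   derived from it.
#' @param registry ROI registry (default: the shipped 176-ROI parcellation).
#' @param n_subjects Subjects per group (default 10, the study design).
#' @return List with \code{control} and \code{exercise} uptake tables,
#'   the \code{registry}, and \code{truth}, the planted difference edges
#'   (data frame with ROI ids and the two target correlations).
#' @export
simulate_study <- function(seed = 1, registry = default_registry(),
                           n_subjects = 10) {
  block_r <- c(CP = 0.55, SNr = 0.80, GPe = 0.85,
               MOTOR = 0.75, PFC = 0.70, TH = 0.80)
  cp <- which(registry$structure == "CP")
  mot <- which(registry$structure == "MOTOR")
  th <- which(registry$structure == "TH")
  pfc <- which(registry$structure == "PFC")
  planted <- data.frame(
    i = c(cp[1:4], th[1:3]),
    j = c(mot[1:4], pfc[1:3]),
    r_control = c(rep(0, 4), rep(0.95, 3)),
    r_exercise = c(rep(0.95, 4), rep(0, 3)))
  blocks <- registry$structure
  endpoints <- unique(c(planted$i, planted$j))
  blocks[endpoints] <- paste0(registry$structure[endpoints], "_planted",
                              seq_along(endpoints))
  cov_spec <- covariance_spec(nrow(registry), blocks,
                              within_block_r = block_r)
  base <- group_spec("control", cov_spec, n_subjects = n_subjects, seed = seed)
  specs <- plant_group_difference(base, planted,
                                  seed_exercise = seed + 10000L)
  truth <- data.frame(roi_i = registry$roi_id[planted$i],
                      roi_j = registry$roi_id[planted$j],
                      r_control = planted$r_control,
                      r_exercise = planted$r_exercise,
                      stringsAsFactors = FALSE)
  list(control = generate_group(specs$control, registry),
       exercise = generate_group(specs$exercise, registry),
       registry = registry, truth = truth)
}
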