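#' Build a signed connectivity graph from an edge set
#'
#' Every registry ROI becomes a node (isolated ROIs included); every edge
#' of the edge set becomes an undirected, sign-attributed edge. No
#' self-loops or parallel edges can arise because edge sets hold unordered
#' distinct ROI pairs.
#'
#' @param edges An \code{edge_set} (within-group or group-difference).
#' @param registry \code{roi_registry} defining the node set and order.
#' @return An \code{igraph} object with node attributes \code{structure},
#'   \code{bregma_mm} and edge attribute \code{sign}.
#' @export
connectivity_graph <- function(edges, registry) {
  g <- igraph::make_empty_graph(n = nrow(registry), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = registry$roi_id)
  g <- igraph::set_vertex_attr(g, "structure", value = registry$structure)
  g <- igraph::set_vertex_attr(g, "bregma_mm", value = registry$bregma_mm)
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges$roi_i, edges$roi_j), registry$roi_id)
    if (length(unknown) > 0) {
      stop(sprintf("edge set references ROI(s) absent from registry: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    g <- igraph::add_edges(g, rbind(edges$roi_i, edges$roi_j),
                           attr = list(sign = edges$sign))
  }
  g
}

match_structure_edges <- function(edges, registry, structure_a, structure_b) {
  si <- registry$structure[match(edges$roi_i, registry$roi_id)]
  sj <- registry$structure[match(edges$roi_j, registry$roi_id)]
  (si == structure_a & sj == structure_b) | (si == structure_b & sj == structure_a)
}

#' Connectivity density for a structure pair
#'
#' The number of reliable connections of a given sign between (or within)
#' two structures, expressed as a percentage of all ROI pairs for that
#' structure pair. With 66 caudoputamen ROIs, 151 positive within-structure
#' edges give 100 * 151 / 2145 = 7.04\%; 10 positive caudoputamen-thalamus
#' edges give 100 * 10 / 1386 = 0.72\%.
#'
#' @param edges An \code{edge_set}.
#' @param registry \code{roi_registry}.
#' @param structure_a,structure_b Structure codes.
#' @param sign "+" or "-".
#' @return Density percentage in [0, 100].
#' @export
connectivity_density <- function(edges, registry, structure_a, structure_b, sign = "+") {
  stopifnot(sign %in% c("+", "-"))
  denom <- pair_count(registry, structure_a, structure_b)
  if (denom == 0) {
    stop(sprintf("no ROI pairs for structures (%s, %s): density undefined",
                 structure_a, structure_b), call. = FALSE)
  }
  if (nrow(edges) == 0) return(0)
  hit <- match_structure_edges(edges, registry, structure_a, structure_b) &
    edges$sign == sign
  100 * sum(hit) / denom
}

#' Signed connectivity-density report over all structure pairs
#'
#' Tabulates, for every unordered structure pair (within-structure pairs
#' included), the positive and negative edge counts, the total ROI pair
#' count, and the corresponding densities — the format of the
#' within/between-structure connectivity-density tables.
#'
#' @param edges An \code{edge_set}.
#' @param registry \code{roi_registry}.
#' @return A \code{density_report} data frame with columns
#'   \code{structure_a}, \code{structure_b}, \code{pair_count},
#'   \code{positive_count}, \code{negative_count}, \code{positive_density},
#'   \code{negative_density}.
#' @export
density_table <- function(edges, registry) {
  structs <- intersect(CBT_STRUCTURES, unique(registry$structure))
  combs <- list()
  for (a_i in seq_along(structs)) {
    for (b_i in a_i:length(structs)) {
      a <- structs[a_i]; b <- structs[b_i]
      denom <- pair_count(registry, a, b)
      if (denom == 0) next
      hit <- if (nrow(edges) > 0) match_structure_edges(edges, registry, a, b) else logical(0)
      npos <- sum(hit & edges$sign == "+")
      nneg <- sum(hit & edges$sign == "-")
      combs[[length(combs) + 1]] <- data.frame(
        structure_a = a, structure_b = b, pair_count = denom,
        positive_count = npos, negative_count = nneg,
        positive_density = 100 * npos / denom,
        negative_density = 100 * nneg / denom,
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, combs)
  rownames(rep) <- NULL
  structure(rep, class = c("density_report", "data.frame"))
}

#' Reshape a density report into a 6 x 6 structure matrix
#'
#' @param report A \code{density_report}.
#' @param sign "+" or "-".
#' @param what "density" (percentage) or "count".
#' @return Symmetric structure-by-structure matrix; within-structure values
#'   on the diagonal.
#' @export
density_matrix <- function(report, sign = "+", what = c("density", "count")) {
  what <- match.arg(what)
  col <- paste0(ifelse(sign == "+", "positive", "negative"), "_",
                ifelse(what == "density", "density", "count"))
  structs <- unique(c(report$structure_a, report$structure_b))
  structs <- intersect(CBT_STRUCTURES, structs)
  m <- matrix(NA_real_, length(structs), length(structs),
              dimnames = list(structs, structs))
  for (i in seq_len(nrow(report))) {
    m[report$structure_a[i], report$structure_b[i]] <- report[[col]][i]
    m[report$structure_b[i], report$structure_a[i]] <- report[[col]][i]
  }
  m
}

#' Node degrees of a connectivity graph
#'
#' Degree is the number of edges linking a node to the rest of the network;
#' positive and negative edges count identically. Isolated nodes have
#' degree 0.
#'
#' @param graph An igraph from \code{\link{connectivity_graph}}.
#' @return A \code{degree_report} data frame (\code{roi_id},
#'   \code{structure}, \code{degree}) in registry (vertex) order.
#' @export
node_degrees <- function(graph) {
  df <- data.frame(roi_id = igraph::V(graph)$name,
                   structure = igraph::V(graph)$structure,
                   degree = as.integer(igraph::degree(graph)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("degree_report", "data.frame"))
}

#' Flag network hubs
#'
#' Hubs are the nodes whose degree ranks in the top \code{fraction}
#' (default 10\%) of the network: exactly \code{ceiling(fraction * N)}
#' nodes are flagged, with ties at the cutoff broken deterministically by
#' registry order. For the shipped 176-ROI network this yields 18 hubs.
#'
#' @param report A \code{degree_report}.
#' @param fraction Top fraction to flag, in (0, 1).
#' @return The report with added \code{rank} (1 = highest degree; ties by
#'   registry order) and logical \code{hub_flag} columns.
#' @export
identify_hubs <- function(report, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(report)
  ord <- order(-report$degree, seq_len(n))
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  report$rank <- rank
  report$hub_flag <- rank <= ceiling(fraction * n)
  report
}

#' Ranked degree changes between two networks
#'
#' Per-node difference in connectivity degree (second minus first group),
#' sorted from the largest gain to the largest loss; ties keep registry
#' order. Gains highlight nodes recruited into the network, losses nodes
#' marginalised.
#'
#' @param report1,report2 \code{degree_report}s over identical node sets in
#'   the same order.
#' @return Data frame (\code{roi_id}, \code{structure}, \code{degree_1},
#'   \code{degree_2}, \code{delta}) sorted by descending \code{delta}.
#' @export
degree_change <- function(report1, report2) {
  if (!identical(report1$roi_id, report2$roi_id)) {
    stop("degree reports cover different node sets", call. = FALSE)
  }
  df <- data.frame(roi_id = report1$roi_id, structure = report1$structure,
                   degree_1 = report1$degree, degree_2 = report2$degree,
                   delta = report2$degree - report1$degree,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$delta, seq_len(nrow(df))), ]
  rownames(df) <- NULL
  df
}

#' Kamada-Kawai layout of a connectivity graph
#'
#' Force-directed ("energised") arrangement placing strongly connected
#' nodes close together. Edges are treated as unweighted and unsigned.
#' Connected nodes are laid out with the Kamada-Kawai algorithm; isolated
#' nodes, which carry no spring information, are placed on a peripheral
#' ring around the layout. Deterministic for a fixed seed.
#'
#' @param graph An igraph from \code{\link{connectivity_graph}}.
#' @param seed Integer seed for the layout initialisation.
#' @return N x 2 coordinate matrix with ROI rownames.
#' @export
layout_network <- function(graph, seed = 1) {
  n <- igraph::vcount(graph)
  coords <- matrix(0, n, 2, dimnames = list(igraph::V(graph)$name, c("x", "y")))
  if (n <= 1) return(coords)
  set.seed(seed)
  comps <- igraph::components(graph)
  sizes <- comps$csize
  multi <- which(sizes > 1)
  # each connected component is energised on its own, normalised to unit RMS
  # radius, then components are spread over well-separated centres
  centres <- matrix(0, length(multi), 2)
  if (length(multi) > 1) {
    theta <- 2 * pi * (seq_along(multi) - 1) / length(multi)
    centres <- 3 * cbind(cos(theta), sin(theta))
  }
  for (ci in seq_along(multi)) {
    members <- which(comps$membership == multi[ci])
    sub <- igraph::induced_subgraph(graph, members)
    xy <- igraph::layout_with_kk(sub)
    xy <- sweep(xy, 2, colMeans(xy))
    rms <- sqrt(mean(rowSums(xy^2)))
    if (rms > 0) xy <- xy / rms
    coords[members, ] <- sweep(xy, 2, centres[ci, ], "+")
  }
  isolated <- which(igraph::degree(graph) == 0)
  if (length(isolated) > 0) {
    placed <- setdiff(seq_len(n), isolated)
    radius <- if (length(placed) > 0) {
      1.3 * max(sqrt(rowSums(coords[placed, , drop = FALSE]^2)), 1)
    } else 1
    theta <- 2 * pi * (seq_along(isolated) - 1) / length(isolated)
    coords[isolated, ] <- cbind(radius * cos(theta), radius * sin(theta))
  }
  coords
}

#' Export a connectivity graph to GraphML
#'
#' Writes the graph with its node attributes (structure, degree, hub flag)
#' and signed edges, ready for external graph tools.
#'
#' @param graph An igraph from \code{\link{connectivity_graph}}.
#' @param path Output file path.
#' @param hub_fraction Top-degree fraction flagged as hubs before export.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(graph, path, hub_fraction = 0.10) {
  rep <- identify_hubs(node_degrees(graph), hub_fraction)
  graph <- igraph::set_vertex_attr(graph, "degree", value = rep$degree)
  graph <- igraph::set_vertex_attr(graph, "hub", value = rep$hub_flag)
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
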