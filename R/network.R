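#' Build an expression-directed interaction network
#'
#' Wraps an undirected edge list plus node expression-direction labels in an
#' igraph graph. Self-loops and duplicate edges are removed.
#'
#' @param edges data frame with two columns of node identifiers.
#' @param directions named character vector (`"up"`, `"down"`); nodes absent
#'   from it are `"unlabeled"`.
#' @return igraph graph with a `direction` vertex attribute.
#' @export
build_network <- function(edges, directions = NULL) {
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  g <- igraph::simplify(g)
  dirs <- rep("unlabeled", igraph::vcount(g))
  if (!is.null(directions)) {
    nm <- igraph::V(g)$name
    hit <- nm %in% names(directions)
    dirs[hit] <- unname(directions[nm[hit]])
  }
  igraph::set_vertex_attr(g, "direction", value = dirs)
}

#' Node-degree summary of a network
#'
#' @param network an igraph graph (or an edge-list data frame).
#' @return list with `degree` (named vector) and `average_degree`
#'   (`2 |E| / |V|`).
#' @export
degree_stats <- function(network) {
  if (!igraph::is_igraph(network)) network <- build_network(network)
  if (igraph::vcount(network) == 0) stop("empty network")
  deg <- igraph::degree(network)
  list(degree = deg, average_degree = 2 * igraph::ecount(network) /
         igraph::vcount(network))
}

#' Classify hub homogeneity
#'
#' Evaluates every node with at least `min_degree` connections and calls it
#' homogeneous when at least `fraction` (inclusive) of its labeled neighbors
#' share one expression direction. Neighbors without a direction label are
#' dropped from the denominator; a hub left with fewer than `min_degree`
#' labeled neighbors is not evaluated.
#'
#' @param network igraph graph with a `direction` vertex attribute (see
#'   [build_network()]).
#' @param min_degree minimum connections for a node to be evaluated.
#' @param fraction inclusive homogeneity threshold on the majority share.
#' @return list with `hubs` (data frame `node`, `degree`, `n_labeled`,
#'   `majority_share`, `homogeneous`) and `counts`
#'   (`c(homogeneous, heterogeneous)`).
#' @export
classify_hub_homogeneity <- function(network, min_degree = 4, fraction = 0.75) {
  deg <- igraph::degree(network)
  cand <- names(deg)[deg >= min_degree]
  dirs <- stats::setNames(igraph::V(network)$direction,
                          igraph::V(network)$name)
  rows <- list()
  for (v in cand) {
    nb <- igraph::neighbors(network, v)$name
    lab <- dirs[nb]
    lab <- lab[lab %in% c("up", "down")]
    if (length(lab) < min_degree) next
    share <- max(mean(lab == "up"), mean(lab == "down"))
    rows[[v]] <- data.frame(node = v, degree = unname(deg[v]),
                            n_labeled = length(lab), majority_share = share,
                            homogeneous = share >= fraction,
                            stringsAsFactors = FALSE)
  }
  hubs <- do.call(rbind, rows) %||%
    data.frame(node = character(), degree = integer(), n_labeled = integer(),
               majority_share = numeric(), homogeneous = logical())
  rownames(hubs) <- NULL
  list(hubs = hubs,
       counts = c(homogeneous = sum(hubs$homogeneous),
                  heterogeneous = sum(!hubs$homogeneous)))
}

#' Compare homogeneity counts between two networks
#'
#' 2x2 comparison of homogeneous/heterogeneous hub counts. Uses the
#' chi-square test (no continuity correction) when every cell expectation is
#' at least 5, otherwise Fisher's exact test.
#'
#' @param counts_a,counts_b length-2 vectors `c(homogeneous, heterogeneous)`.
#' @return list with `p_value`, `method`, `table`.
#' @export
compare_homogeneity <- function(counts_a, counts_b) {
  tab <- rbind(a = counts_a, b = counts_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero-margin table")
  }
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expd >= 5)) {
    list(p_value = stats::chisq.test(tab, correct = FALSE)$p.value,
         method = "chi-square", table = tab)
  } else {
    list(p_value = stats::fisher.test(tab)$p.value,
         method = "fisher_exact", table = tab)
  }
}
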