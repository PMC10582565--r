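#' Build the whole-brain connectivity network
#'
#' One undirected edge per region pair with at least one retained record.
#' By default only connectivity-strength indicators (FC, SC, gFCD, lFCD,
#' EC, ReHo) contribute edges; network-model metrics and unknown indicators
#' are bookkept but excluded. Each edge carries `multiplicity` (number of
#' supporting records) and `sign` (+1/-1 where the supporting records are
#' unanimous, NA otherwise; run [resolve_conflicts()] first for a fully
#' signed network). Nodes are the regions that appear in at least one
#' retained record.
#'
#' @param records a signed [record_set()] (merged and conflict-resolved).
#' @param include_indicators character vector of indicators that may form
#'   edges.
#' @return an igraph object of class `"brain_network"`, vertices named by
#'   region code.
#' @examples
#' recs <- generate_records(synthetic_spec(seed = 1))$records
#' net <- build_network(recs)
#' net
#' @export
build_network <- function(records,
                          include_indicators = CONNECTIVITY_INDICATORS) {
  if (!nrow(records)) stop_jmenet("build_network: empty record set")
  keep <- records$indicator %in% include_indicators
  df <- as.data.frame(records)[keep, , drop = FALSE]
  if (!nrow(df)) stop_jmenet("build_network: no records with edge-forming indicators")
  if (anyNA(df$direction)) {
    stop_jmenet("build_network: records must be signed (run sign_records first)")
  }
  key <- pair_key(df$region_a, df$region_b)
  agg <- do.call(rbind, lapply(split(df, key), function(rows) {
    s <- unique(rows$direction)
    data.frame(region_a = rows$region_a[1], region_b = rows$region_b[1],
               sign = if (length(s) == 1) s else NA_integer_,
               multiplicity = nrow(rows), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$region_a, agg$region_b), , drop = FALSE]
  nodes <- sort(unique(c(agg$region_a, agg$region_b)))
  g <- igraph::graph_from_data_frame(agg, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  as_brain_network(g)
}

#' Coerce an igraph object to a brain network
#'
#' Validates the brain-network invariants: undirected, simple (no
#' self-loops or multi-edges), named vertices; canonicalizes vertex order
#' by name so that identically-labelled graphs behave identically under
#' seeded algorithms.
#'
#' @param g an igraph object with named vertices.
#' @return the canonicalized graph with class `"brain_network"` prepended.
#' @export
as_brain_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop_jmenet("brain networks are undirected")
  if (any(igraph::which_loop(g))) stop_jmenet("self-loops are not allowed")
  if (any(igraph::which_multiple(g))) stop_jmenet("multi-edges are not allowed")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  nm <- igraph::V(g)$name
  g <- igraph::permute(g, match(nm, sort(nm)))
  class(g) <- unique(c("brain_network", class(g)))
  g
}

#' @export
print.brain_network <- function(x, ...) {
  signed <- "sign" %in% igraph::edge_attr_names(x) &&
    !anyNA(igraph::E(x)$sign)
  cat(sprintf("<brain_network> %d regions, %d edges%s\n",
              igraph::vcount(x), igraph::ecount(x),
              if (signed) " (signed)" else ""))
  invisible(x)
}

#' Degree centrality
#'
#' Number of direct connections of each region. `mode = "simple"` counts
#' distinct neighbors; `mode = "multiplicity"` counts supporting records
#' (the sum of edge multiplicities), for the reading in which the degree
#' filter operates on record-level connections.
#'
#' @param net a [build_network()] result (or any igraph graph).
#' @param mode `"simple"` or `"multiplicity"`.
#' @return named numeric vector of degrees.
#' @export
degree_centrality <- function(net, mode = c("simple", "multiplicity")) {
  mode <- match.arg(mode)
  if (mode == "simple" ||
      !"multiplicity" %in% igraph::edge_attr_names(net)) {
    d <- igraph::degree(net)
  } else {
    d <- igraph::strength(net, weights = igraph::E(net)$multiplicity)
  }
  d
}

#' Betweenness centrality
#'
#' For each region i, the sum over unordered pairs \{j, k\} (both distinct
#' from i) of the fraction of shortest j-k paths that pass through i;
#' disconnected pairs contribute 0. Normalization divides by
#' (g-1)(g-2)/2, the number of pairs, giving values in [0, 1].
#' `mode = "raw-count"` instead counts the number of shortest j-k paths
#' passing through i (the literal path-count reading of the formula) rather
#' than Freeman's fraction.
#'
#' @param net a brain network (igraph).
#' @param normalized divide by (g-1)(g-2)/2?
#' @param mode `"fractional"` (default, Brandes-style) or `"raw-count"`.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = TRUE,
                                   mode = c("fractional", "raw-count")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(net)
  if (mode == "fractional") {
    b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  } else {
    b <- path_count_betweenness(net)
  }
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    b <- if (denom > 0) b / denom else b * 0
  }
  b
}

# Literal path-count betweenness: number of shortest j-k paths through i,
# summed over unordered pairs {j,k}. Computed from BFS distances and
# shortest-path counts (walk counting on distance layers).
path_count_betweenness <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, type = "both"))
  n <- nrow(A)
  out <- setNames(numeric(n), igraph::V(net)$name)
  if (n < 3) return(out)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- diag(1, n)
  P <- diag(1, n)
  for (k in seq_len(n - 1)) {
    P <- P %*% A
    new <- is.infinite(D) & P > 0
    D[new] <- k
    S[new] <- P[new]
  }
  for (i in seq_len(n)) {
    on_path <- outer(D[, i], D[i, ], "+") == D & is.finite(D)
    on_path[i, ] <- FALSE
    on_path[, i] <- FALSE
    diag(on_path) <- FALSE
    through <- outer(S[, i], S[i, ], "*")
    out[i] <- sum(through[on_path]) / 2
  }
  out
}

#' Centrality profile of a network
#'
#' @inheritParams degree_centrality
#' @param degree_mode passed to [degree_centrality()].
#' @param cb_mode passed to [betweenness_centrality()].
#' @return data frame of class `"centrality_profile"` with columns `node`,
#'   `degree`, `cb_raw`, `cb_norm`.
#' @export
centrality_profile <- function(net, degree_mode = "simple",
                               cb_mode = "fractional") {
  cb_raw <- betweenness_centrality(net, normalized = FALSE, mode = cb_mode)
  cb_norm <- betweenness_centrality(net, normalized = TRUE, mode = cb_mode)
  out <- data.frame(
    node = igraph::V(net)$name,
    degree = as.numeric(degree_centrality(net, degree_mode)),
    cb_raw = as.numeric(cb_raw),
    cb_norm = as.numeric(cb_norm),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' Label-propagation community detection
#'
#' Asynchronous label propagation with seeded random node order and
#' tie-breaking: every node ends up with a label shared by a maximal number
#' of its neighbors. Deterministic given `seed`; disconnected components
#' never share a label.
#'
#' @param net a brain network (igraph).
#' @param seed integer seed.
#' @return list of class `"community_assignment"` with `labels` (named
#'   integer vector, community ids contiguous from 0), `n_communities`,
#'   `seed`.
#' @export
label_propagation <- function(net, seed) {
  stopifnot(is_count(seed))
  memb <- withr::with_seed(as.integer(seed), {
    igraph::membership(igraph::cluster_label_prop(net))
  })
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- igraph::V(net)$name
  structure(list(labels = labels,
                 n_communities = length(unique(labels)),
                 seed = as.integer(seed)),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> %d communities over %d nodes (seed %d)\n",
              x$n_communities, length(x$labels), x$seed))
  invisible(x)
}

#' Seeded force-directed layout
#'
#' Fruchterman-Reingold spring layout, centered on the origin and
#' deterministic given `seed`.
#'
#' @param net a brain network (igraph).
#' @param seed integer seed.
#' @return numeric matrix, one row per node (named), two columns.
#' @export
spring_layout <- function(net, seed) {
  stopifnot(is_count(seed))
  xy <- withr::with_seed(as.integer(seed), igraph::layout_with_fr(net))
  xy <- sweep(xy, 2, colMeans(xy))
  rownames(xy) <- igraph::V(net)$name
  colnames(xy) <- c("x", "y")
  xy
}

#' Write a network as GraphML
#' @param net a brain network.
#' @param path output file.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a network as an edge-list CSV
#'
#' Columns `region_a,region_b,sign,multiplicity`.
#' @param net a brain network.
#' @param path output file.
#' @export
write_network_csv <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  p <- canonical_pair(el$from, el$to)
  out <- data.frame(region_a = p$a, region_b = p$b,
                    sign = el$sign %||% rep(NA_integer_, nrow(el)),
                    multiplicity = el$multiplicity %||% rep(1L, nrow(el)))
  out <- out[order(out$region_a, out$region_b), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a network from an edge-list CSV
#' @param path CSV with columns `region_a,region_b,sign,multiplicity`.
#' @return a brain network.
#' @export
read_network_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_a", "region_b") %in% names(df)))
  if (is.null(df$sign)) df$sign <- NA_integer_
  if (is.null(df$multiplicity)) df$multiplicity <- 1L
  nodes <- sort(unique(c(df$region_a, df$region_b)))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  as_brain_network(g)
}
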