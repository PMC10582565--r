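#' White-matter tract map
#'
#' A declared anatomical adjacency: the unordered region pairs with a
#' direct fiber connection. Tract maps are inputs (typically YAML), not
#' derived from imaging.
#'
#' @param pairs two-column matrix/data frame of region codes, or a list of
#'   length-2 character vectors.
#' @return data frame of class `"tract_map"` with columns `region_a`,
#'   `region_b` (canonical order, no duplicates, no self-pairs).
#' @export
tract_map <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      stopifnot(length(p) == 2)
      data.frame(region_a = p[[1]], region_b = p[[2]],
                 stringsAsFactors = FALSE)
    }))
  }
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("region_a", "region_b")
  if (any(pairs$region_a == pairs$region_b)) {
    stop_jmenet("tract_map: self-pairs are not allowed")
  }
  p <- canonical_pair(pairs$region_a, pairs$region_b)
  out <- unique(data.frame(region_a = p$a, region_b = p$b,
                           stringsAsFactors = FALSE))
  out <- out[order(out$region_a, out$region_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tract_map", "data.frame")
  out
}

#' Read a tract map from YAML
#'
#' Expects a `tracts:` key holding a list of region-code pairs, e.g.
#' `tracts: [[Tha, BG], [Tha, Cere]]`.
#'
#' @param path YAML file.
#' @return a [tract_map()].
#' @export
read_tract_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tracts)) stop_jmenet("tract YAML needs a 'tracts:' key")
  tract_map(cfg$tracts)
}

tract_graph <- function(tracts) {
  nodes <- sort(unique(c(tracts$region_a, tracts$region_b)))
  igraph::graph_from_data_frame(tracts, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Signed core network constrained to tract adjacency
#'
#' @param edges data frame with columns `region_a`, `region_b`, `sign`
#'   (+1/-1).
#' @param tracts a [tract_map()]; every edge must be a tract pair. All
#'   tract-map regions become nodes even when unused by an edge.
#' @return igraph of class `c("signed_core_network", "brain_network")`.
#' @export
signed_core_network <- function(edges, tracts) {
  tracts <- tract_map(tracts[, c("region_a", "region_b")])
  edges <- as.data.frame(edges)
  stopifnot(all(c("region_a", "region_b", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop_jmenet("signed_core_network: every edge needs sign +1 or -1")
  }
  p <- canonical_pair(edges$region_a, edges$region_b)
  edges$region_a <- p$a
  edges$region_b <- p$b
  ek <- pair_key(edges$region_a, edges$region_b)
  tk <- pair_key(tracts$region_a, tracts$region_b)
  if (!all(ek %in% tk)) {
    stop_jmenet("signed_core_network: edge(s) outside the tract map: %s",
                paste(setdiff(ek, tk), collapse = ", "))
  }
  nodes <- sort(unique(c(tracts$region_a, tracts$region_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("region_a", "region_b", "sign")], directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- as_brain_network(g)
  class(g) <- unique(c("signed_core_network", class(g)))
  g
}

edge_sign <- function(network, a, b) {
  eid <- igraph::get_edge_ids(network, c(a, b))
  if (eid == 0) return(NA_integer_)
  as.integer(igraph::E(network)$sign[eid])
}

#' Propagate a connectivity-change sign along a path
#'
#' The transitive sign rule: a positive change between A and B combined
#' with a negative change between B and C implies a negative change
#' between A and C. Along a longer path the implied sign is the product of
#' the edge signs.
#'
#' @param path character vector of region codes (at least 3, i.e. two
#'   edges); consecutive regions must be edges of `network`.
#' @param network a [signed_core_network()].
#' @return +1 or -1.
#' @export
propagate_sign <- function(path, network) {
  if (length(path) < 3) stop_jmenet("propagate_sign: path needs >= 2 edges")
  signs <- vapply(seq_len(length(path) - 1), function(i) {
    s <- edge_sign(network, path[i], path[i + 1])
    if (is.na(s)) {
      stop_jmenet("propagate_sign: %s-%s is not an edge", path[i], path[i + 1])
    }
    s
  }, integer(1))
  as.integer(prod(signs))
}

#' Sign implied for a region pair by tract-constrained propagation
#'
#' A direct edge carries its own sign. Otherwise the sign is propagated
#' over every shortest path between the two regions; when distinct
#' shortest paths imply different signs, or the pair is disconnected, the
#' result is indeterminate (`NA`).
#'
#' @param pair character vector of two region codes in the network.
#' @param network a [signed_core_network()].
#' @return +1, -1, or `NA` (indeterminate).
#' @export
implied_sign <- function(pair, network) {
  stopifnot(length(pair) == 2)
  nodes <- igraph::V(network)$name
  if (!all(pair %in% nodes)) {
    stop_jmenet("implied_sign: region(s) not in network: %s",
                paste(setdiff(pair, nodes), collapse = ", "))
  }
  direct <- edge_sign(network, pair[1], pair[2])
  if (!is.na(direct)) return(direct)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(network, from = pair[1], to = pair[2]))$vpaths
  if (!length(sp)) return(NA_integer_)
  signs <- vapply(sp, function(vp) {
    propagate_sign(igraph::V(network)$name[as.integer(vp)], network)
  }, integer(1))
  u <- unique(signs)
  if (length(u) == 1) u else NA_integer_
}

#' Score observed changes against a tract-constrained network
#'
#' Each observed signed change is satisfied when the network's implied
#' sign for its pair equals the observed sign; an indeterminate implied
#' sign counts as violated. Reports the satisfied fraction over evaluated
#' changes and, when `n_excluded` pre-excluded (conflicting) changes are
#' supplied, the fraction over all pre-exclusion changes.
#'
#' @param network a [signed_core_network()].
#' @param observed a signed [record_set()] restricted to core pairs.
#' @param n_excluded number of changes excluded before evaluation (e.g.
#'   conflicting study conclusions); they enter only the pre-exclusion
#'   denominator.
#' @return list of class `"consistency_report"`: `satisfied` and
#'   `violated` data frames (`region_a`, `region_b`, `observed`,
#'   `implied`), `fraction`, `fraction_pre_exclusion`, `n_evaluated`,
#'   `n_excluded`.
#' @export
consistency_report <- function(network, observed, n_excluded = 0) {
  if (!nrow(observed)) stop_jmenet("consistency_report: no observed changes")
  if (anyNA(observed$direction)) {
    stop_jmenet("consistency_report: observed records must be signed")
  }
  nodes <- igraph::V(network)$name
  out_nodes <- setdiff(unique(c(observed$region_a, observed$region_b)), nodes)
  if (length(out_nodes)) {
    stop_jmenet("consistency_report: observed region(s) outside core: %s",
                paste(out_nodes, collapse = ", "))
  }
  implied <- vapply(seq_len(nrow(observed)), function(i) {
    implied_sign(c(observed$region_a[i], observed$region_b[i]), network)
  }, integer(1))
  res <- data.frame(region_a = observed$region_a,
                    region_b = observed$region_b,
                    observed = observed$direction,
                    implied = implied,
                    stringsAsFactors = FALSE)
  ok <- !is.na(implied) & implied == observed$direction
  n_eval <- nrow(res)
  out <- list(satisfied = res[ok, , drop = FALSE],
              violated = res[!ok, , drop = FALSE],
              fraction = sum(ok) / n_eval,
              fraction_pre_exclusion =
                (sum(ok) + n_excluded) / (n_eval + n_excluded),
              n_evaluated = n_eval,
              n_excluded = as.integer(n_excluded))
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> %d/%d observed changes satisfied (%.1f%%)\n",
              nrow(x$satisfied), x$n_evaluated, 100 * x$fraction))
  if (x$n_excluded > 0) {
    cat(sprintf("including %d pre-excluded change(s): %.1f%%\n",
                x$n_excluded, 100 * x$fraction_pre_exclusion))
  }
  if (nrow(x$violated)) {
    cat("violated:\n")
    print(x$violated, row.names = FALSE)
  }
  invisible(x)
}

# connected spanning edge-subsets of the tract graph, as logical masks
spanning_subsets <- function(tg) {
  m <- igraph::ecount(tg)
  masks <- list()
  for (code in seq_len(2^m) - 1L) {
    mask <- as.logical(bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)))
    sub <- igraph::subgraph_from_edges(tg, igraph::E(tg)[mask],
                                       delete.vertices = FALSE)
    if (igraph::is_connected(sub)) masks[[length(masks) + 1L]] <- mask
  }
  masks
}

#' Search for the maximally consistent simplified network
#'
#' Enumerates connected spanning edge-subsets of the tract map with every
#' sign assignment that agrees with directly observed edge signs, scores
#' each candidate with [consistency_report()], and returns a network
#' maximizing the satisfied fraction. Ties break toward fewer edges, then
#' lexicographic signed-edge signature. Exhaustive search requires at most
#' 8 core regions; larger cores use seeded greedy hill-climbing with
#' restarts.
#'
#' @param tracts a [tract_map()].
#' @param observed a signed, conflict-free [record_set()] on core pairs.
#' @param mode `"exhaustive"` or `"greedy"`.
#' @param n_excluded passed to [consistency_report()].
#' @param seed seed for greedy restarts (ignored in exhaustive mode).
#' @param n_restarts greedy restarts.
#' @return list with `network` (the best [signed_core_network()]) and
#'   `report` (its [consistency_report()]).
#' @export
search_max_consistent <- function(tracts, observed,
                                  mode = c("exhaustive", "greedy"),
                                  n_excluded = 0, seed = 1, n_restarts = 20) {
  mode <- match.arg(mode)
  tracts <- tract_map(tracts[, c("region_a", "region_b")])
  tg <- tract_graph(tracts)
  n_core <- igraph::vcount(tg)
  if (mode == "exhaustive" && n_core > 8) {
    stop_jmenet("exhaustive search supports at most 8 core regions; use mode = 'greedy'")
  }
  if (anyNA(observed$direction)) {
    stop_jmenet("search_max_consistent: observed records must be signed")
  }
  if (nrow(detect_conflicts(observed))) {
    stop_jmenet("search_max_consistent: observed records contain conflicting pairs")
  }

  # unanimous observed sign per pair, pinned where the pair is a tract edge
  obs_key <- pair_key(observed$region_a, observed$region_b)
  pair_sign <- tapply(observed$direction, obs_key, function(s) unique(s))
  tk <- pair_key(tracts$region_a, tracts$region_b)
  pinned <- setNames(rep(NA_integer_, length(tk)), tk)
  hit <- intersect(tk, names(pair_sign))
  pinned[hit] <- unlist(pair_sign[hit])

  candidate <- function(mask, signs) {
    signed_core_network(
      data.frame(region_a = tracts$region_a[mask],
                 region_b = tracts$region_b[mask],
                 sign = signs, stringsAsFactors = FALSE),
      tracts)
  }
  edge_signature <- function(mask, signs) {
    paste(sort(paste0(tk[mask], ":", signs)), collapse = ";")
  }
  score <- function(net) consistency_report(net, observed, n_excluded)

  # a candidate is (mask over tract edges, signs for masked edges)
  evaluate <- function(mask, signs) {
    net <- candidate(mask, signs)
    list(network = net, report = score(net), mask = mask,
         signs = as.integer(signs), n_edges = sum(mask),
         sig = edge_signature(mask, signs))
  }
  better <- function(cand, state) {
    if (is.null(state)) return(TRUE)
    if (cand$report$fraction != state$report$fraction) {
      return(cand$report$fraction > state$report$fraction)
    }
    if (cand$n_edges != state$n_edges) return(cand$n_edges < state$n_edges)
    cand$sig < state$sig
  }
  connected_mask <- function(mask) {
    sub <- igraph::subgraph_from_edges(tg, igraph::E(tg)[mask],
                                       delete.vertices = FALSE)
    igraph::is_connected(sub)
  }

  best <- NULL
  if (mode == "exhaustive") {
    masks <- spanning_subsets(tg)
    if (!length(masks)) stop_jmenet("no connected spanning tract subset exists")
    for (mask in masks) {
      idx <- which(mask)
      free <- is.na(pinned[tk[idx]])
      n_free <- sum(free)
      for (code in seq_len(2^n_free) - 1L) {
        signs <- pinned[tk[idx]]
        if (n_free > 0) {
          bits <- as.logical(bitwAnd(code, bitwShiftL(1L, seq_len(n_free) - 1L)))
          signs[free] <- ifelse(bits, 1L, -1L)
        }
        cand <- evaluate(mask, signs)
        if (better(cand, best)) best <- cand
      }
    }
  } else {
    m <- igraph::ecount(tg)
    if (!connected_mask(rep(TRUE, m))) {
      stop_jmenet("no connected spanning tract subset exists")
    }
    for (r in seq_len(n_restarts)) {
      cur <- withr::with_seed(derive_seed(seed, paste0("restart", r)), {
        mask <- rep(TRUE, m)
        signs <- pinned[tk]
        signs[is.na(signs)] <- sample(c(-1L, 1L), sum(is.na(signs)),
                                      replace = TRUE)
        cur <- evaluate(mask, signs[mask])
        repeat {
          improved <- FALSE
          for (e in seq_len(m)) {
            if (cur$mask[e]) {
              # try flipping a free sign
              pos <- sum(cur$mask[seq_len(e)])
              if (is.na(pinned[tk[e]])) {
                s2 <- cur$signs
                s2[pos] <- -s2[pos]
                cand <- evaluate(cur$mask, s2)
                if (better(cand, cur)) { cur <- cand; improved <- TRUE }
              }
              # try dropping the edge (keep spanning connectivity)
              m2 <- cur$mask
              m2[e] <- FALSE
              if (connected_mask(m2)) {
                cand <- evaluate(m2, cur$signs[-pos])
                if (better(cand, cur)) { cur <- cand; improved <- TRUE }
              }
            } else {
              # try adding the edge with its pinned or either free sign
              m2 <- cur$mask
              m2[e] <- TRUE
              pos <- sum(m2[seq_len(e)])
              s_try <- if (is.na(pinned[tk[e]])) c(-1L, 1L) else pinned[tk[e]]
              for (s in s_try) {
                s2 <- append(cur$signs, s, after = pos - 1L)
                cand <- evaluate(m2, s2)
                if (better(cand, cur)) { cur <- cand; improved <- TRUE }
              }
            }
          }
          if (!improved) break
        }
        cur
      })
      if (better(cur, best)) best <- cur
    }
  }
  list(network = best$network, report = best$report)
}

#' Mean core betweenness across network modes
#'
#' Arithmetic mean of each region's normalized betweenness across a
#' collection of core-network modes sharing one node set.
#'
#' @param modes list of networks (e.g. [signed_core_network()]s or reduced
#'   configurations' networks).
#' @return named numeric vector, one mean per region.
#' @export
mean_core_betweenness <- function(modes) {
  if (!length(modes)) stop_jmenet("mean_core_betweenness: no modes given")
  node_sets <- lapply(modes, function(m) sort(igraph::V(m)$name))
  if (length(unique(vapply(node_sets, paste, "", collapse = ","))) != 1) {
    stop_jmenet("mean_core_betweenness: node sets differ across modes")
  }
  cbs <- vapply(modes, function(m) {
    betweenness_centrality(m, normalized = TRUE)[node_sets[[1]]]
  }, numeric(length(node_sets[[1]])))
  rowMeans(matrix(cbs, nrow = length(node_sets[[1]]),
                  dimnames = list(node_sets[[1]], NULL)))
}
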