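#' Canonical signature of a network configuration
#'
#' A configuration is identified by its surviving node set plus induced
#' edge set; the signature is invariant under node/edge input order
#' (everything is sorted before serialization).
#'
#' @param net a brain network (igraph, named vertices).
#' @return character scalar.
#' @export
graph_signature <- function(net) {
  nodes <- sort(igraph::V(net)$name)
  el <- igraph::as_edgelist(net)
  edges <- character(0)
  if (nrow(el)) edges <- sort(pair_key(el[, 1], el[, 2]))
  paste0("n:", paste(nodes, collapse = ","),
         ";e:", paste(edges, collapse = ","))
}

#' Termination nodes of a network
#'
#' A termination node cannot affect the rest of the network: it lies on no
#' shortest path between any other pair of nodes, i.e. its normalized
#' betweenness is exactly 0. Leaves of a star, every node of a complete
#' graph, and the endpoints of a path are all termination nodes.
#'
#' @param net a brain network (igraph).
#' @return character vector of node names.
#' @export
find_termination_nodes <- function(net) {
  cb <- betweenness_centrality(net, normalized = TRUE)
  names(cb)[cb == 0]
}

# termination nodes under a community partition: betweenness is evaluated
# inside each community's induced subgraph, plus globally on the whole
# (active) graph so that every survivor keeps positive global betweenness.
community_termination_nodes <- function(net, labels) {
  term <- find_termination_nodes(net)
  for (lab in unique(labels)) {
    members <- names(labels)[labels == lab]
    sub <- igraph::induced_subgraph(net, members)
    cb <- betweenness_centrality(sub, normalized = TRUE)
    term <- union(term, names(cb)[cb == 0])
  }
  sort(term)
}

#' Stochastic node reduction (method 1)
#'
#' Iteratively prunes nodes that cannot affect the rest of the network.
#' Each iteration (a) partitions the current surviving subgraph into
#' communities by seeded label propagation, (b) computes betweenness within
#' each community's induced subgraph (and globally), and (c) removes the
#' termination nodes -- those with betweenness 0 -- from further
#' computation. Iteration stops when a full pass removes nothing
#' (`converged = "stable"`; every survivor then has positive betweenness
#' in the reduced network) or when the termination set covers the whole
#' surviving set (`converged = "terminal"`: a fully terminal attractor
#' such as a complete graph, kept as the final configuration rather than
#' wiped). The result is the surviving node set with its induced
#' subgraph; a pass that leaves a single node is an error of class
#' `"jmenet_degenerate"`.
#'
#' The per-iteration label-propagation seed is derived by hashing the base
#' seed together with the canonical signature of the current surviving
#' subgraph. This makes the operation deterministic given `seed`,
#' reproducible across sessions, and idempotent: reducing a returned
#' configuration's network again with the same seed returns the same
#' signature, because the converged subgraph hashes to the same partition
#' that declared it stable.
#'
#' @param net a brain network with at least 3 nodes.
#' @param seed integer seed controlling label-propagation order and
#'   tie-breaking.
#' @return list of class `"network_configuration"`: `signature`, `network`
#'   (induced subgraph on survivors), `profile` (centralities of the
#'   reduced network), `category`, `max_cb_nodes`, `seed`, `n_iterations`,
#'   `converged` (`"stable"` or `"terminal"`).
#' @seealso [enumerate_configurations()] to tally signatures over many
#'   seeds.
#' @export
reduce_method1 <- function(net, seed) {
  stopifnot(is_count(seed))
  if (igraph::vcount(net) < 3) {
    stop_jmenet("reduce_method1: need at least 3 nodes")
  }
  surviving <- igraph::V(net)$name
  g_act <- as_brain_network(net)
  iter <- 0L
  converged <- NULL
  repeat {
    iter <- iter + 1L
    sig <- graph_signature(g_act)
    sub_seed <- derive_seed(seed, sig)
    comm <- label_propagation(g_act, sub_seed)
    term <- community_termination_nodes(g_act, comm$labels)
    if (!length(term)) {
      converged <- "stable"  # no termination node left: all survivors matter
      break
    }
    if (length(term) == length(surviving)) {
      # fully terminal partition (e.g. a complete graph): the whole
      # configuration is an attractor; halt here rather than wipe it
      converged <- "terminal"
      break
    }
    surviving <- setdiff(surviving, term)
    if (length(surviving) < 2) {
      stop_jmenet(
        "reduce_method1: network collapsed to %d surviving node(s) (seed %d)",
        length(surviving), seed, class = "jmenet_degenerate")
    }
    g_act <- as_brain_network(igraph::induced_subgraph(net, surviving))
  }
  profile <- centrality_profile(g_act)
  cat_info <- categorize_configuration(profile)
  structure(list(signature = graph_signature(g_act),
                 network = g_act,
                 profile = profile,
                 category = cat_info$category,
                 max_cb_nodes = cat_info$max_cb_nodes,
                 seed = as.integer(seed),
                 n_iterations = iter,
                 converged = converged),
            class = "network_configuration")
}

#' @export
print.network_configuration <- function(x, ...) {
  cat(sprintf("<network_configuration> %d nodes, %d edges, category %d (seed %d)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              x$category, x$seed))
  cat("defining nodes:", paste(x$max_cb_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a reduced configuration by its betweenness profile
#'
#' Category 1: exactly one node with normalized betweenness above
#' `cb_high`. Category 2: at least two nodes in (`cb_mid`, `cb_high`] and
#' none above `cb_high`. Category 3: all nodes below `cb_mid`. Profiles
#' falling in none of these classes (e.g. a single node in the middle
#' band) are assigned category 3 with a warning; precedence is 1 > 2 > 3.
#'
#' @param profile a [centrality_profile()] (needs column `cb_norm`).
#' @param cb_high,cb_mid category thresholds (defaults 0.8 and 0.5).
#' @return list with `category` (integer 1/2/3) and `max_cb_nodes` (the
#'   nodes attaining the category-defining values).
#' @export
categorize_configuration <- function(profile, cb_high = 0.8, cb_mid = 0.5) {
  cb <- profile$cb_norm
  node <- profile$node
  high <- cb > cb_high
  mid <- cb > cb_mid & cb <= cb_high
  if (sum(high) == 1) {
    return(list(category = 1L, max_cb_nodes = node[high]))
  }
  if (sum(high) == 0 && sum(mid) >= 2) {
    return(list(category = 2L, max_cb_nodes = node[mid]))
  }
  peak <- node[cb == max(cb)]
  if (all(cb < cb_mid)) {
    return(list(category = 3L, max_cb_nodes = peak))
  }
  warning(sprintf(
    "profile falls in no category (e.g. %d node(s) > %.2g, %d in (%.2g, %.2g]); assigning category 3",
    sum(high), cb_high, sum(mid), cb_mid, cb_high))
  list(category = 3L, max_cb_nodes = peak)
}

#' Enumerate reduced configurations over seeded runs
#'
#' Runs [reduce_method1()] with seeds `base_seed, ..., base_seed + n_runs
#' - 1`, tallies the distinct configuration signatures, and tests the
#' empirical distribution over observed signatures for uniformity with a
#' chi-square test. Runs that collapse below 2 nodes are excluded with a
#' logged count.
#'
#' @param net a brain network.
#' @param n_runs number of seeded runs (>= 1).
#' @param base_seed first seed.
#' @return list of class `"configuration_distribution"`: `counts` (named by
#'   signature), `probabilities`, `n_runs`, `n_excluded`, `seeds`,
#'   `configurations` (one representative per signature), `categories`,
#'   `chisq` (list with `statistic`, `df`, `p_value`).
#' @export
enumerate_configurations <- function(net, n_runs, base_seed) {
  stopifnot(is_count(n_runs), n_runs >= 1, is_count(base_seed))
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  counts <- integer(0)
  reps <- list()
  excluded <- 0L
  for (s in seeds) {
    cfg <- tryCatch(reduce_method1(net, s), jmenet_degenerate = function(e) NULL)
    if (is.null(cfg)) {
      excluded <- excluded + 1L
      next
    }
    sig <- cfg$signature
    if (is.na(match(sig, names(counts)))) {
      counts[sig] <- 0L
      reps[[sig]] <- cfg
    }
    counts[sig] <- counts[sig] + 1L
  }
  if (excluded > 0) {
    message(sprintf("enumerate_configurations: %d of %d runs degenerate (excluded)",
                    excluded, n_runs))
  }
  total <- sum(counts)
  chisq <- if (length(counts) >= 2) {
    ct <- suppressWarnings(chisq.test(as.numeric(counts)))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
  } else {
    # a single observed signature is trivially uniform over itself
    list(statistic = 0, df = 0L, p_value = 1)
  }
  structure(list(counts = counts,
                 probabilities = if (total > 0) counts / total else counts,
                 n_runs = as.integer(n_runs),
                 n_excluded = excluded,
                 seeds = seeds,
                 configurations = reps,
                 categories = vapply(reps, function(cfg) cfg$category,
                                     integer(1)),
                 chisq = chisq),
            class = "configuration_distribution")
}

#' @export
print.configuration_distribution <- function(x, ...) {
  cat(sprintf("<configuration_distribution> %d distinct configurations over %d runs (%d excluded)\n",
              length(x$counts), x$n_runs, x$n_excluded))
  if (length(x$counts)) {
    cat(sprintf("probabilities: %s\n",
                paste(sprintf("%.3f", sort(x$probabilities, decreasing = TRUE)),
                      collapse = ", ")))
    cat(sprintf("chi-square uniformity: X2 = %.3f, df = %d, p = %.4f\n",
                x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  }
  invisible(x)
}

#' Extract the high-degree core network (node reduction method 2)
#'
#' Induced subgraph on nodes whose degree strictly exceeds
#' `degree_threshold` (default 10), with degree computed per
#' `degree_mode` (distinct neighbors or record multiplicities).
#'
#' @inheritParams degree_centrality
#' @param degree_threshold integer threshold (default 10).
#' @param degree_mode passed to [degree_centrality()].
#' @return a brain network on the core regions.
#' @export
core_filter <- function(net, degree_threshold = 10,
                        degree_mode = c("simple", "multiplicity")) {
  degree_mode <- match.arg(degree_mode)
  d <- degree_centrality(net, degree_mode)
  keep <- names(d)[d > degree_threshold]
  if (!length(keep)) {
    stop_jmenet(paste0(
      "core_filter: no node has %s degree > %s; ",
      "lower the threshold or switch degree mode"),
      degree_mode, degree_threshold, class = "jmenet_empty_core")
  }
  as_brain_network(igraph::induced_subgraph(net, keep))
}

#' Enumerate core-network modes
#'
#' Same contract as [enumerate_configurations()], applied to the core
#' network extracted by [core_filter()].
#'
#' @param core a nonempty core brain network.
#' @inheritParams enumerate_configurations
#' @return a `"configuration_distribution"`.
#' @export
enumerate_core_modes <- function(core, n_runs, base_seed) {
  if (igraph::vcount(core) == 0) stop_jmenet("enumerate_core_modes: empty core")
  enumerate_configurations(core, n_runs, base_seed)
}
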