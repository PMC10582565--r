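#' Specification for a synthetic literature corpus
#'
#' Describes the study conditions the generator emulates: a corpus of
#' ~15 studies reporting signed region-pair connectivity changes over 21
#' regions, with a planted 6-region high-degree core and signs drawn from
#' a structurally balanced assignment, optionally corrupted at a
#' controlled frustration rate.
#'
#' Pair classes: core-involving pairs (at least one endpoint in the
#' planted core) are Bernoulli(`p_core_edge`); periphery-periphery pairs
#' are Bernoulli(`p_periphery_edge`). The expected core simple degree,
#' `p_core_edge * (n_regions - 1)`, must exceed
#' `degree_threshold`, and the generator tops up rare shortfalls so that
#' the planted core property (simple degree > threshold) always holds.
#'
#' @param n_regions number of regions (default 21).
#' @param n_studies number of studies (default 15).
#' @param core_size planted core size (default 6).
#' @param p_core_edge probability a core-involving pair gets a record
#'   (default 0.7).
#' @param p_periphery_edge probability a periphery-periphery pair gets a
#'   record (default 0.05).
#' @param frustration_rate probability an observed sign contradicts the
#'   planted balanced assignment (default 0).
#' @param conflict_rate fraction of connected pairs that additionally
#'   receive an opposite-sign record from a second study (default 0).
#' @param degree_threshold the core-identification threshold the
#'   calibration must exceed (default 10).
#' @param seed integer seed; generation is bit-reproducible given the
#'   seed.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_regions = 21, n_studies = 15, core_size = 6,
                           p_core_edge = 0.7, p_periphery_edge = 0.05,
                           frustration_rate = 0, conflict_rate = 0,
                           degree_threshold = 10, seed = 1) {
  stopifnot(is_count(n_regions), is_count(n_studies), is_count(core_size),
            is_count(seed), core_size < n_regions,
            p_core_edge >= 0, p_core_edge <= 1,
            p_periphery_edge >= 0, p_periphery_edge <= 1,
            frustration_rate >= 0, frustration_rate <= 1,
            conflict_rate >= 0, conflict_rate <= 1)
  expected_core_degree <- p_core_edge * (n_regions - 1)
  if (expected_core_degree <= degree_threshold) {
    stop_jmenet(paste0(
      "infeasible calibration: expected core degree %.2f <= threshold %d; ",
      "raise p_core_edge or n_regions"),
      expected_core_degree, degree_threshold)
  }
  structure(list(n_regions = n_regions, n_studies = n_studies,
                 core_size = core_size, p_core_edge = p_core_edge,
                 p_periphery_edge = p_periphery_edge,
                 frustration_rate = frustration_rate,
                 conflict_rate = conflict_rate,
                 degree_threshold = degree_threshold,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic planted structure shared by generate_records and
# generate_tract_map: region codes, core membership, balanced node spins
plant_core <- function(spec) {
  withr::with_seed(derive_seed(spec$seed, "plant"), {
    regions <- sprintf("R%02d", seq_len(spec$n_regions))
    core <- sort(sample(regions, spec$core_size))
    spins <- setNames(sample(c(-1L, 1L), spec$n_regions, replace = TRUE),
                      regions)
    list(regions = regions, core = core, spins = spins)
  })
}

#' Generate a synthetic record corpus with planted ground truth
#'
#' Draws the edge set by pair class (see [synthetic_spec()]), signs each
#' edge from the planted balanced node assignment (sign = product of the
#' endpoint spins), flips signs independently at `frustration_rate`,
#' assigns records to studies with cohort sizes drawn uniformly from
#' 10-60, and plants `conflict_rate` opposite-sign duplicate records. A
#' fraction of records carry a raw correlation (whose Fisher z has the
#' planted sign) instead of a qualitative direction, exercising the
#' indicator-conversion path.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (a [record_set()]), `truth` (planted core,
#'   spins, edge table with true/observed signs and flip locations,
#'   conflicted pairs) and `registry` (a synthetic [region_registry()]).
#' @export
generate_records <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  planted <- plant_core(spec)
  regions <- planted$regions
  core <- planted$core
  spins <- planted$spins

  withr::with_seed(derive_seed(spec$seed, "records"), {
    pairs <- t(utils::combn(regions, 2))
    a <- pairs[, 1]
    b <- pairs[, 2]
    in_core_a <- a %in% core
    in_core_b <- b %in% core
    pair_class <- ifelse(in_core_a | in_core_b, "core_involving", "periphery")
    p_edge <- c(core_involving = spec$p_core_edge,
                periphery = spec$p_periphery_edge)[pair_class]
    drawn <- runif(length(p_edge)) < p_edge
    has_edge <- drawn

    # top up: the planted core property is simple degree > threshold
    deg <- function() {
      e <- c(a[has_edge], b[has_edge])
      tab <- table(factor(e, levels = regions))
      setNames(as.integer(tab), regions)
    }
    for (node in core) {
      d <- deg()[node]
      while (d <= spec$degree_threshold) {
        cand <- which(!has_edge & (a == node | b == node))
        if (!length(cand)) break
        has_edge[sample(cand, 1)] <- TRUE
        d <- d + 1L
      }
    }

    ea <- a[has_edge]
    eb <- b[has_edge]
    true_sign <- spins[ea] * spins[eb]
    flipped <- runif(length(ea)) < spec$frustration_rate
    obs_sign <- ifelse(flipped, -true_sign, true_sign)

    studies <- sprintf("S%02d", seq_len(spec$n_studies))
    n_patients <- setNames(sample(10:60, spec$n_studies, replace = TRUE),
                           studies)
    n_controls <- setNames(sample(10:60, spec$n_studies, replace = TRUE),
                           studies)
    modality <- setNames(sample(MODALITIES, spec$n_studies, replace = TRUE,
                                prob = c(0.6, 0.1, 0.1, 0.1, 0.1)), studies)

    n_edges <- length(ea)
    study_of <- sample(studies, n_edges, replace = TRUE)
    indicator <- sample(CONNECTIVITY_INDICATORS, n_edges, replace = TRUE,
                        prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))

    make_rows <- function(a, b, sgn, study, ind, as_raw) {
      raw_r <- ifelse(as_raw, sgn * runif(length(a), 0.1, 0.8), NA_real_)
      data.frame(study_id = study,
                 modality = unname(modality[study]),
                 indicator = ind,
                 region_a = a, region_b = b,
                 direction = ifelse(as_raw, NA_integer_, sgn),
                 raw_r = raw_r,
                 n_patients = unname(n_patients[study]),
                 n_controls = unname(n_controls[study]),
                 stringsAsFactors = FALSE)
    }

    as_raw <- runif(n_edges) < 0.3
    df <- make_rows(ea, eb, obs_sign, study_of, indicator, as_raw)

    # concordant replication in a second study (~15% of edges)
    rep_idx <- which(runif(n_edges) < 0.15)
    if (length(rep_idx)) {
      other <- vapply(study_of[rep_idx], function(s) {
        sample(setdiff(studies, s), 1)
      }, character(1))
      df <- rbind(df, make_rows(ea[rep_idx], eb[rep_idx], obs_sign[rep_idx],
                                other, indicator[rep_idx],
                                rep(FALSE, length(rep_idx))))
    }

    # planted conflicts: an opposite-sign record from yet another study
    n_conflict <- round(spec$conflict_rate * n_edges)
    conflict_pairs <- character(0)
    if (n_conflict > 0) {
      cidx <- sample(n_edges, n_conflict)
      conflict_pairs <- pair_key(ea[cidx], eb[cidx])
      used <- split(df$study_id, pair_key(df$region_a, df$region_b))
      other <- vapply(cidx, function(i) {
        sample(setdiff(studies, used[[pair_key(ea[i], eb[i])]]), 1)
      }, character(1))
      df <- rbind(df, make_rows(ea[cidx], eb[cidx], -obs_sign[cidx], other,
                                indicator[cidx], rep(FALSE, n_conflict)))
    }

    df <- df[order(df$study_id, df$region_a, df$region_b, df$indicator), ]
    records <- record_set(df, provenance = sprintf("synthetic(seed=%d)",
                                                   spec$seed))
    registry <- region_registry(
      data.frame(code = regions,
                 name = sprintf("synthetic region %s", regions),
                 stringsAsFactors = FALSE))
    truth <- list(
      core = core,
      spins = spins,
      edges = data.frame(region_a = ea, region_b = eb,
                         class = pair_class[has_edge],
                         topped_up = !drawn[has_edge],
                         true_sign = unname(true_sign),
                         observed_sign = unname(obs_sign),
                         flipped = flipped, stringsAsFactors = FALSE),
      pairs = data.frame(region_a = a, region_b = b, class = pair_class,
                         drawn = drawn, edge = has_edge,
                         stringsAsFactors = FALSE),
      conflict_pairs = conflict_pairs,
      spec = spec
    )
    list(records = records, truth = truth, registry = registry)
  })
}

#' Generate a tract map over the planted core
#'
#' A connected anatomical adjacency over the planted core regions: a
#' seeded random spanning tree plus extra core pairs at probability 0.4.
#' Any subset of core pairs is consistent with the planted balanced sign
#' assignment (edge signs are products of node spins), so the map's
#' support always admits a frustration-free signing.
#'
#' @param spec a [synthetic_spec()].
#' @return a [tract_map()] over the planted core regions.
#' @export
generate_tract_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  core <- plant_core(spec)$core
  withr::with_seed(derive_seed(spec$seed, "tracts"), {
    k <- length(core)
    if (k < 2) stop_jmenet("generate_tract_map: core_size must be >= 2")
    ord <- sample(core)
    edges <- data.frame(region_a = character(0), region_b = character(0),
                        stringsAsFactors = FALSE)
    for (i in 2:k) {
      j <- if (i == 2) 1 else sample(i - 1, 1)
      edges <- rbind(edges, data.frame(region_a = ord[j], region_b = ord[i],
                                       stringsAsFactors = FALSE))
    }
    if (k > 2) {
      extra <- t(utils::combn(core, 2))
      key <- pair_key(extra[, 1], extra[, 2])
      have <- pair_key(edges$region_a, edges$region_b)
      for (i in seq_len(nrow(extra))) {
        if (!key[i] %in% have && runif(1) < 0.4) {
          edges <- rbind(edges, data.frame(region_a = extra[i, 1],
                                           region_b = extra[i, 2],
                                           stringsAsFactors = FALSE))
        }
      }
    }
    tract_map(edges)
  })
}
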