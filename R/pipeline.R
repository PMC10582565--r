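#' Pipeline configuration
#'
#' A serializable bundle of paths, seeds, thresholds, and mode flags for
#' [run_pipeline()]. Configs round-trip losslessly through YAML
#' ([write_pipeline_config()] / [load_pipeline_config()]).
#'
#' @param records path to a records CSV/JSON (may be `NULL` when records
#'   are passed to [run_pipeline()] directly).
#' @param region_config optional YAML with `regions:`/`merge:` sections.
#' @param tracts optional tract-map YAML.
#' @param out_dir output directory.
#' @param seed master seed; all stochastic stages derive their seeds from
#'   it.
#' @param n_runs node-reduction runs on the whole-brain network.
#' @param core_runs node-reduction runs on the core network.
#' @param degree_threshold core degree threshold (default 10).
#' @param cb_high,cb_mid configuration category thresholds (0.8, 0.5).
#' @param degree_mode `"simple"` or `"multiplicity"`.
#' @param cb_mode `"fractional"` or `"raw-count"`.
#' @param search_mode `"exhaustive"` or `"greedy"`.
#' @param conflict_policy `"exclude"` or `"majority"`.
#' @param tau sensitivity threshold on |z| for qualitative conversion.
#' @param include_nonconnectivity also build edges from `network_metric` /
#'   `unknown` indicators?
#' @param write_plots write PNG layout plots?
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(records = NULL, region_config = NULL,
                            tracts = NULL, out_dir = "jmenet-out",
                            seed = 1, n_runs = 500, core_runs = 100,
                            degree_threshold = 10, cb_high = 0.8,
                            cb_mid = 0.5, degree_mode = "simple",
                            cb_mode = "fractional",
                            search_mode = "exhaustive",
                            conflict_policy = "exclude", tau = 0,
                            include_nonconnectivity = FALSE,
                            write_plots = FALSE) {
  cfg <- list(
    paths = list(records = records, region_config = region_config,
                 tracts = tracts, out_dir = out_dir),
    seed = as.integer(seed),
    n_runs = as.integer(n_runs),
    core_runs = as.integer(core_runs),
    thresholds = list(degree_threshold = as.integer(degree_threshold),
                      cb_high = cb_high, cb_mid = cb_mid, tau = tau),
    modes = list(degree = degree_mode, cb = cb_mode, search = search_mode),
    flags = list(conflict_policy = conflict_policy,
                 include_nonconnectivity = include_nonconnectivity,
                 write_plots = write_plots)
  )
  stopifnot(cfg$modes$degree %in% c("simple", "multiplicity"),
            cfg$modes$cb %in% c("fractional", "raw-count"),
            cfg$modes$search %in% c("exhaustive", "greedy"),
            cfg$flags$conflict_policy %in% c("exclude", "majority"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    records = raw$paths$records, region_config = raw$paths$region_config,
    tracts = raw$paths$tracts, out_dir = raw$paths$out_dir %||% "jmenet-out",
    seed = raw$seed %||% 1, n_runs = raw$n_runs %||% 500,
    core_runs = raw$core_runs %||% 100,
    degree_threshold = raw$thresholds$degree_threshold %||% 10,
    cb_high = raw$thresholds$cb_high %||% 0.8,
    cb_mid = raw$thresholds$cb_mid %||% 0.5,
    tau = raw$thresholds$tau %||% 0,
    degree_mode = raw$modes$degree %||% "simple",
    cb_mode = raw$modes$cb %||% "fractional",
    search_mode = raw$modes$search %||% "exhaustive",
    conflict_policy = raw$flags$conflict_policy %||% "exclude",
    include_nonconnectivity = isTRUE(raw$flags$include_nonconnectivity),
    write_plots = isTRUE(raw$flags$write_plots)
  )
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes ingest, region merging, qualitative signing, conflict
#' handling, network construction, centrality profiling, community
#' detection, stochastic node-reduction configuration enumeration,
#' core extraction, core-mode enumeration, and tract-constrained sign
#' consistency, writing a JSON report, centrality CSV and GraphML
#' networks (plus optional PNG layouts) under the configured output
#' directory.
#'
#' @param config a [pipeline_config()].
#' @param records optional [record_set()] overriding
#'   `config$paths$records`.
#' @param tracts optional [tract_map()] overriding `config$paths$tracts`;
#'   when neither is given the tract-consistency stage is skipped.
#' @param registry optional [region_registry()] override.
#' @return the report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config, records = NULL, tracts = NULL,
                         registry = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- ingest ---------------------------------------------------------
  merge_map <- default_merge_map()
  if (is.null(registry)) {
    if (!is.null(config$paths$region_config)) {
      rc <- read_region_config(config$paths$region_config)
      registry <- rc$registry
      if (length(rc$merge_map)) merge_map <- rc$merge_map
    } else {
      registry <- region_registry()
    }
  }
  if (is.null(records)) {
    if (is.null(config$paths$records)) {
      stop_jmenet("[ingest] no records: set config$paths$records or pass records")
    }
    records <- read_records(config$paths$records)
  }
  stage_log("ingest", "%d records, %d studies, seed %d", nrow(records),
            length(unique(records$study_id)), config$seed)
  cohort <- summarize_cohort(records)

  # -- merge + sign + conflicts --------------------------------------
  merged <- merge_regions(records, merge_map, registry)
  signed <- sign_records(merged, tau = config$thresholds$tau)
  conflicts <- detect_conflicts(signed)
  resolved <- resolve_conflicts(signed, policy = config$flags$conflict_policy)
  stage_log("conflicts", "%d conflicted pair(s), %d record(s) excluded",
            nrow(conflicts), attr(resolved, "n_excluded_records"))

  # -- build + centrality + communities ------------------------------
  include <- CONNECTIVITY_INDICATORS
  if (isTRUE(config$flags$include_nonconnectivity)) include <- INDICATORS
  net <- build_network(resolved, include_indicators = include)
  stage_log("build", "%d nodes, %d edges", igraph::vcount(net),
            igraph::ecount(net))
  profile <- centrality_profile(net, degree_mode = config$modes$degree,
                                cb_mode = config$modes$cb)
  comm <- label_propagation(net, derive_seed(config$seed, "lpa"))
  layout <- spring_layout(net, derive_seed(config$seed, "layout"))

  # -- node reduction: configurations --------------------------------
  dist <- enumerate_configurations(net, config$n_runs,
                                   derive_seed(config$seed, "reduce"))
  stage_log("reduce", "%d distinct configurations over %d runs (%d excluded)",
            length(dist$counts), dist$n_runs, dist$n_excluded)

  # -- core extraction + core modes ----------------------------------
  core <- core_filter(net, config$thresholds$degree_threshold,
                      config$modes$degree)
  stage_log("core", "core regions: %s",
            paste(sort(igraph::V(core)$name), collapse = ", "))
  core_modes <- enumerate_core_modes(core, config$core_runs,
                                     derive_seed(config$seed, "core"))

  # -- tract-constrained consistency ---------------------------------
  consistency <- NULL
  mean_cb <- NULL
  if (is.null(tracts) && !is.null(config$paths$tracts)) {
    tracts <- read_tract_map(config$paths$tracts)
  }
  if (!is.null(tracts)) {
    tract_nodes <- unique(c(tracts$region_a, tracts$region_b))
    obs <- resolved[resolved$region_a %in% tract_nodes &
                      resolved$region_b %in% tract_nodes &
                      resolved$indicator %in% include, , drop = FALSE]
    core_conf <- conflicts[conflicts$region_a %in% tract_nodes &
                             conflicts$region_b %in% tract_nodes, ,
                           drop = FALSE]
    n_excluded <- if (nrow(core_conf)) {
      sum(core_conf$n_increase + core_conf$n_decrease)
    } else 0L
    if (nrow(obs)) {
      found <- search_max_consistent(tracts, obs, mode = config$modes$search,
                                     n_excluded = n_excluded,
                                     seed = derive_seed(config$seed, "search"))
      consistency <- found$report
      stage_log("consistency", "%d/%d observed changes satisfied (%.1f%%)",
                nrow(consistency$satisfied), consistency$n_evaluated,
                100 * consistency$fraction)
      write_network_graphml(found$network,
                            file.path(out_dir, "consistent-core.graphml"))
    }
  }

  # mean betweenness of core regions across core modes retaining the
  # full core node set (fall back to the core network itself)
  full_core <- sort(igraph::V(core)$name)
  full_modes <- Filter(function(cfg) {
    identical(sort(igraph::V(cfg$network)$name), full_core)
  }, core_modes$configurations)
  mean_cb <- if (length(full_modes)) {
    mean_core_betweenness(lapply(full_modes, `[[`, "network"))
  } else {
    mean_core_betweenness(list(core))
  }

  # -- write artifacts ------------------------------------------------
  write.csv(profile, file.path(out_dir, "centrality.csv"), row.names = FALSE)
  write_network_graphml(net, file.path(out_dir, "network.graphml"))
  write_network_csv(net, file.path(out_dir, "network-edges.csv"))
  write_network_graphml(core, file.path(out_dir, "core.graphml"))
  if (isTRUE(config$flags$write_plots)) {
    try(plot_network_png(net, comm, layout, profile,
                         file.path(out_dir, "network.png")), silent = TRUE)
  }

  report <- list(
    seed = config$seed,
    config = unclass(config),
    cohort = list(n_studies = cohort$n_studies,
                  total_patients = cohort$total_patients,
                  total_controls = cohort$total_controls,
                  modality_counts = as.list(cohort$modality_counts),
                  indicator_counts = as.list(cohort$indicator_counts)),
    network = list(n_nodes = igraph::vcount(net),
                   n_edges = igraph::ecount(net),
                   n_conflicted_pairs = nrow(conflicts)),
    communities = list(n_communities = comm$n_communities,
                       labels = as.list(comm$labels)),
    centrality = profile,
    configurations = list(
      n_distinct = length(dist$counts),
      counts = as.list(dist$counts),
      probabilities = as.list(dist$probabilities),
      categories = as.list(dist$categories),
      n_excluded = dist$n_excluded,
      chisq = dist$chisq),
    core = list(nodes = sort(igraph::V(core)$name),
                n_nodes = igraph::vcount(core)),
    core_modes = list(
      n_distinct = length(core_modes$counts),
      counts = as.list(core_modes$counts),
      probabilities = as.list(core_modes$probabilities),
      n_excluded = core_modes$n_excluded,
      chisq = core_modes$chisq),
    mean_core_cb = as.list(mean_cb),
    consistency = if (!is.null(consistency)) {
      list(fraction = consistency$fraction,
           fraction_pre_exclusion = consistency$fraction_pre_exclusion,
           n_evaluated = consistency$n_evaluated,
           n_excluded = consistency$n_excluded,
           satisfied = consistency$satisfied,
           violated = consistency$violated)
    },
    timestamp = format(Sys.time(), tz = "UTC")
  )
  validate_report(report)
  write_json_atomic(report, file.path(out_dir, "report.json"))
  stage_log("report", "written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}

# PNG layout plot: node radius proportional to betweenness, color per
# community (all figure content derives from report data)
plot_network_png <- function(net, comm, layout, profile, path) {
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  size <- 5 + 25 * profile$cb_norm[match(igraph::V(net)$name, profile$node)]
  col <- comm$labels[igraph::V(net)$name] + 1L
  plot(net, layout = layout, vertex.size = size, vertex.color = col,
       vertex.label.cex = 0.8)
  invisible(path)
}

#' Validate a pipeline report against the shipped schema
#'
#' Structural validation: required top-level fields must be present with
#' the JSON types declared in `inst/schema/report-schema.json`.
#'
#' @param report a report list as produced by [run_pipeline()].
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "report-schema.json",
                             package = "jmenet")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  for (field in names(schema$required)) {
    type <- schema$required[[field]]
    if (!field %in% names(report)) {
      stop_jmenet("report is missing required field '%s'", field)
    }
    val <- report[[field]]
    ok <- switch(type,
                 number = is.numeric(val) && length(val) == 1,
                 string = is.character(val) && length(val) == 1,
                 object = is.list(val),
                 "object?" = is.null(val) || is.list(val),
                 TRUE)
    if (!ok) {
      stop_jmenet("report field '%s' is not of type %s", field, type)
    }
  }
  invisible(TRUE)
}
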