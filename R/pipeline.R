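#' Assemble a pipeline run configuration
#'
#' Inputs may be file paths (CSV) or in-memory tibbles; tables generated by
#' [generate_movement_data()] can be passed straight through. Analysis
#' options default to the conventions used throughout the package and are
#' recorded in the run manifest.
#'
#' @param movements Movement table (path or tibble).
#' @param gazetteer,aliases,response Optional supporting tables (path or
#'   tibble); the response table enables exact completeness filtering.
#' @param schema Optional column mapping for [read_movements()].
#' @param scenario Completeness scenario name (`"any"`, `"most"`, `"all"`).
#' @param months Ordered month labels of the study window; inferred from
#'   the data when `NULL`.
#' @param out_dir Output directory; `NULL` disables file output.
#' @param neighbourhood,loyalty_pooling,absent_nodes Loyalty conventions,
#'   see [loyalty_series()].
#' @param top_fraction Highly-connected cut-off, see [top_connected()].
#' @param reciprocity_variant,degree_convention,degree_excess Measure
#'   conventions, see [measure_table()].
#' @param fallback_region Passed to [standardise_locations()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(movements, gazetteer = NULL, aliases = NULL,
                       response = NULL, schema = NULL, scenario = "most",
                       months = NULL, out_dir = NULL,
                       neighbourhood = "union", loyalty_pooling = "nodes",
                       absent_nodes = "zero", top_fraction = 0.10,
                       reciprocity_variant = "edge",
                       degree_convention = "out_in", degree_excess = FALSE,
                       fallback_region = "out_of_province") {
  structure(mget(names(formals(run_config))), class = "run_config")
}

load_table <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  readr::read_csv(x, progress = FALSE, show_col_types = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("equinet_stage_error", "error", "condition"),
                   list(message = paste0("stage '", name, "' failed: ",
                                         conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Run the full movement network analysis pipeline
#'
#' Executes ingest, completeness filtering, inclusion criteria, location
#' standardisation and typing, monthly network construction, static
#' measures, temporal loyalty/similarity, and distance/region-flow
#' summaries. When `out_dir` is set, writes the measure table, distance
#' table, loyalty and similarity tables, region flows, exclusion report,
#' location register, per-month GraphML files, a CSV edge list, and a JSON
#' run manifest. Output is deterministic: re-running on identical inputs
#' reproduces the files byte for byte.
#'
#' @param config A [run_config()].
#' @return A list with all intermediate and final objects plus `manifest`
#'   (stage counts, options, config hash).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ing <- stage("ingest", {
    mv <- config$movements
    if (is.character(mv)) {
      read_movements(mv, schema = config$schema)
    } else {
      list(records = tibble::as_tibble(mv),
           rejects = tibble::tibble(reject_reason = character()))
    }
  })
  response <- stage("ingest", load_table(config$response))
  gazetteer <- stage("ingest", load_table(config$gazetteer))
  aliases <- stage("ingest", load_table(config$aliases))

  filtered <- stage("completeness", filter_by_completeness(
    ing$records, response_table = response, scenario = config$scenario,
    months = config$months))
  participants <- attr(filtered, "participants")

  inc <- stage("inclusion", apply_inclusion_criteria(filtered))
  std <- stage("standardise", standardise_locations(
    inc$kept, aliases = aliases, gazetteer = gazetteer,
    fallback_region = config$fallback_region))
  types <- stage("classify", classify_location_types(std$records,
                                                     std$locations))
  networks <- stage("build", build_monthly_networks(
    std$records, std$locations, months = config$months,
    location_types = types))

  measures <- stage("measures", measure_table(
    networks, reciprocity_variant = config$reciprocity_variant,
    degree_convention = config$degree_convention,
    degree_excess = config$degree_excess))
  nonempty <- Filter(function(g) igraph::ecount(g) > 0, networks)
  loyalty <- stage("temporal", if (length(nonempty) >= 2)
    loyalty_series(nonempty, mode = config$neighbourhood,
                   absent = config$absent_nodes,
                   pooling = config$loyalty_pooling))
  similarity <- stage("temporal", if (length(nonempty) >= 2)
    similarity_series(nonempty, fraction = config$top_fraction))
  distances <- stage("geo", movement_distances(std$records, std$locations))
  flows <- stage("geo", region_flow_series(std$records, std$locations))

  manifest <- list(
    package_version = as.character(utils::packageVersion("equinet")),
    scenario = if (is.character(config$scenario)) config$scenario else
      config$scenario$name,
    options = config[c("neighbourhood", "loyalty_pooling", "absent_nodes",
                       "top_fraction", "reciprocity_variant",
                       "degree_convention", "degree_excess",
                       "fallback_region")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    counts = list(
      ingested = nrow(ing$records), rejected = nrow(ing$rejects),
      after_completeness = nrow(filtered),
      participants_retained = length(participants),
      kept = nrow(inc$kept), excluded = nrow(inc$excluded),
      locations = nrow(std$locations),
      months = length(networks)))

  result <- list(records = std$records, rejects = ing$rejects,
                 excluded = inc$excluded, locations = std$locations,
                 location_types = types, networks = networks,
                 measures = measures, loyalty = loyalty,
                 similarity = similarity, distances = distances,
                 flows = flows, participants = participants,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_outputs(result, config$out_dir)
  result
}

# Write the paper-shaped CSV outputs plus GraphML networks and manifest.
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_csv(x, file.path(dir, name))
  w(result$measures, "measures.csv")
  w(result$distances, "distances.csv")
  w(result$flows$flows, "region_flows.csv")
  w(result$flows$within, "region_within.csv")
  if (!is.null(result$loyalty)) {
    w(result$loyalty$per_node, "loyalty.csv")
    w(result$loyalty$per_pair, "loyalty_summary.csv")
  }
  if (!is.null(result$similarity)) w(result$similarity$pairs, "similarity.csv")
  w(result$locations, "locations.csv")
  w(result$excluded, "exclusions.csv")
  w(result$records, "records_clean.csv")
  write_networks(result$networks, file.path(dir, "networks"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Repeat the analysis under several data-completeness scenarios
#'
#' Runs the pipeline once per scenario and tabulates the monthly measure
#' rows side by side, with differences of each scenario's node and edge
#' counts against the first scenario listed.
#'
#' @param config A [run_config()]; its `scenario` field is overridden.
#' @param scenarios Character vector of scenario names.
#' @return A list with `runs` (one pipeline result per scenario),
#'   `measures` (long tibble with a `scenario` column) and `differences`
#'   (per month/scenario node and edge count differences vs the first
#'   scenario).
#' @export
compare_scenarios <- function(config, scenarios = c("any", "most", "all")) {
  runs <- lapply(scenarios, function(s) {
    cfg <- config
    cfg$scenario <- s
    if (!is.null(cfg$out_dir)) cfg$out_dir <- file.path(cfg$out_dir, s)
    run_pipeline(cfg)
  })
  names(runs) <- scenarios
  measures <- dplyr::bind_rows(lapply(scenarios, function(s)
    dplyr::mutate(runs[[s]]$measures, scenario = s, .before = 1)))
  base <- runs[[1]]$measures
  differences <- dplyr::bind_rows(lapply(scenarios, function(s) {
    m <- runs[[s]]$measures
    tibble::tibble(scenario = s, month = m$month,
                   d_nodes = m$n_nodes - base$n_nodes[match(m$month,
                                                            base$month)],
                   d_edges = m$n_edges - base$n_edges[match(m$month,
                                                            base$month)])
  }))
  list(runs = runs, measures = measures, differences = differences)
}
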