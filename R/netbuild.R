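#' Build monthly directed contact networks from movement records
#'
#' Aggregates movements into one directed, unweighted network per calendar
#' month. Each movement contributes an outgoing edge (origin to destination)
#' in its departure month and, when a return date exists, an incoming edge
#' (destination back to origin) in the month of the return — a trip spanning
#' a month boundary therefore contributes to two monthly networks, so both
#' directed movements are conserved. Permanent moves (no return date)
#' contribute only the outgoing edge. Parallel movements between the same
#' pair collapse to a single edge (how many horses moved is not considered)
#' and self-loops are dropped. Nodes are active locations only: every node
#' has at least one incident edge that month.
#'
#' Node attributes carried on each network: `type` (the monthly location
#' type from [classify_location_types()]), `region`, and `discipline` — the
#' disciplines of the horses touching the node that month, reduced to
#' `competition`, `leisure`, or `both`.
#'
#' @param records Standardised, filtered movement records.
#' @param locations Location register from [standardise_locations()].
#' @param months Ordered character vector of month labels defining the
#'   study window; defaults to the months spanned by the departure dates.
#'   A return falling after the last month contributes no edge and raises a
#'   warning (its outgoing edge is kept).
#' @param location_types Optional precomputed [classify_location_types()]
#'   table; computed from `records` when `NULL`.
#' @return A named list of `igraph` objects, one per month (possibly
#'   edgeless), each with graph attribute `month`.
#' @export
build_monthly_networks <- function(records, locations, months = NULL,
                                   location_types = NULL) {
  dep_m <- month_label(records$departure_date)
  if (is.null(months)) {
    if (!nrow(records)) return(list())
    r <- range(records$departure_date, na.rm = TRUE)
    months <- month_label(seq(as.Date(format(r[1], "%Y-%m-01")),
                              as.Date(format(r[2], "%Y-%m-01")),
                              by = "1 month"))
  }
  if (is.null(location_types))
    location_types <- classify_location_types(records, locations)

  ret_m <- ifelse(is.na(records$return_date), NA_character_,
                  month_label(records$return_date))
  edges <- dplyr::bind_rows(
    tibble::tibble(month = dep_m, from = records$origin_location,
                   to = records$destination_location),
    tibble::tibble(month = ret_m[!is.na(ret_m)],
                   from = records$destination_location[!is.na(ret_m)],
                   to = records$origin_location[!is.na(ret_m)]))
  beyond <- !edges$month %in% months
  if (any(beyond)) {
    warning(sum(beyond), " movement edge(s) fall outside the study months ",
            "and are dropped (trips returning after the last month keep ",
            "only their outgoing edge)")
    edges <- edges[!beyond, , drop = FALSE]
  }
  edges <- dplyr::distinct(edges[edges$from != edges$to, , drop = FALSE])

  # disciplines of horses touching each location per month (via either
  # endpoint of any of their movements active that month)
  disc <- dplyr::bind_rows(
    tibble::tibble(month = dep_m,
                   location_id = records$origin_location,
                   discipline = records$discipline),
    tibble::tibble(month = dep_m,
                   location_id = records$destination_location,
                   discipline = records$discipline),
    tibble::tibble(month = ret_m[!is.na(ret_m)],
                   location_id = records$origin_location[!is.na(ret_m)],
                   discipline = records$discipline[!is.na(ret_m)]),
    tibble::tibble(month = ret_m[!is.na(ret_m)],
                   location_id = records$destination_location[!is.na(ret_m)],
                   discipline = records$discipline[!is.na(ret_m)])) |>
    dplyr::filter(!is.na(.data$discipline)) |>
    dplyr::distinct() |>
    dplyr::summarise(
      discipline = if (dplyr::n() > 1) "both" else .data$discipline[1],
      .by = c("month", "location_id"))

  out <- lapply(months, function(m) {
    em <- edges[edges$month == m, c("from", "to"), drop = FALSE]
    g <- igraph::graph_from_data_frame(em, directed = TRUE)
    nodes <- igraph::V(g)$name
    ty <- location_types[location_types$month == m, , drop = FALSE]
    igraph::V(g)$type <- ty$type[match(nodes, ty$location_id)]
    igraph::V(g)$region <- locations$region[match(nodes,
                                                  locations$location_id)]
    dm <- disc[disc$month == m, , drop = FALSE]
    igraph::V(g)$discipline <- dm$discipline[match(nodes, dm$location_id)]
    g <- igraph::set_graph_attr(g, "month", m)
    g
  })
  names(out) <- months
  out
}

#' Long edge table for a list of monthly networks
#'
#' @param networks Named list of monthly networks.
#' @return A tibble with columns `month`, `from`, `to`.
#' @export
as_edge_table <- function(networks) {
  dplyr::bind_rows(lapply(networks, function(g) {
    el <- igraph::as_edgelist(g)
    tibble::tibble(month = igraph::graph_attr(g, "month"),
                   from = el[, 1], to = el[, 2])
  }))
}

#' Write monthly networks to GraphML and/or CSV edge lists
#'
#' @param networks Named list of monthly networks.
#' @param dir Output directory (created if needed).
#' @param format Any of `"graphml"`, `"csv"`.
#' @return Invisibly, the paths written.
#' @export
write_networks <- function(networks, dir, format = c("graphml", "csv")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("graphml" %in% format) {
    for (m in names(networks)) {
      p <- file.path(dir, paste0("network-", m, ".graphml"))
      igraph::write_graph(networks[[m]], p, format = "graphml")
      paths <- c(paths, p)
    }
  }
  if ("csv" %in% format) {
    p <- file.path(dir, "edges.csv")
    readr::write_csv(as_edge_table(networks), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
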