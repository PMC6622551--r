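# Jaccard overlap of two sets; NA when both are empty.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Neighbour set of a node in a directed network
#'
#' @param net An `igraph` network.
#' @param node Node name.
#' @param mode `"union"` (in- and out-neighbours, default) or `"out"`.
#' @return Character vector of neighbour names (self excluded); empty when
#'   the node is absent from the network.
#' @export
neighbour_set <- function(net, node, mode = c("union", "out")) {
  mode <- match.arg(mode)
  if (!node %in% igraph::V(net)$name) return(character())
  nb <- igraph::neighbors(net, node,
                          mode = if (mode == "union") "all" else "out")
  setdiff(unique(nb$name), node)
}

#' Loyalty of a node between two consecutive monthly networks
#'
#' The Jaccard index of the node's neighbour sets in the two months: the
#' proportion of its direct contacts that are preserved. 1 means horses
#' from the location travelled to (or arrived from) exactly the same set of
#' locations in both months; a node absent from one month scores 0.
#'
#' @param net_t,net_t1 Networks for two (consecutive) months.
#' @param node Node name.
#' @param mode Neighbourhood convention, see [neighbour_set()].
#' @return Jaccard value in \[0, 1\], or `NA` when the node has an empty
#'   neighbourhood in both months (loyalty is then undefined).
#' @export
node_loyalty <- function(net_t, net_t1, node, mode = "union") {
  jaccard(neighbour_set(net_t, node, mode), neighbour_set(net_t1, node, mode))
}

#' Proportion of preserved contacts between two monthly networks
#'
#' The Jaccard index of the two months' contact sets: the fraction of
#' location pairs in contact in either month that were in contact in both.
#' With `directed = FALSE` (default) a contact is an unordered dyad, so a
#' trip counts as preserved regardless of which direction survived.
#' This is the network-level companion to per-node loyalty
#' ([node_loyalty()]): one value per month pair.
#'
#' @param net_t,net_t1 Networks for two (consecutive) months.
#' @param directed Compare directed edge sets instead of unordered dyads.
#' @return Jaccard value in \[0, 1\]; `NA` if both networks are edgeless.
#' @export
edge_loyalty <- function(net_t, net_t1, directed = FALSE) {
  eset <- function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) return(character())
    if (!directed) el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    unique(paste(el[, 1], el[, 2], sep = "\r"))
  }
  jaccard(eset(net_t), eset(net_t1))
}

#' Loyalty series over consecutive monthly networks
#'
#' Computes per-node loyalty for every consecutive month pair, eligible
#' nodes being those with a non-empty neighbourhood in at least one of the
#' two months. With `absent = "zero"` (default) a node present in only one
#' month scores 0 — a location that stops being visited has preserved no
#' contacts; `absent = "drop"` restricts to nodes present in both months.
#' The overall summary pools all per-node values across pairs
#' (`pooling = "nodes"`, default) or summarises the per-pair medians
#' (`pooling = "pair_medians"`).
#'
#' @param networks Ordered named list of monthly networks (at least 2).
#' @param mode Neighbourhood convention, see [neighbour_set()].
#' @param absent `"zero"` or `"drop"`.
#' @param pooling `"nodes"` or `"pair_medians"`.
#' @return A list with `per_node` (tibble: `month_t`, `month_t1`, `node`,
#'   `loyalty`), `per_pair` (tibble with the pair-level proportion of
#'   preserved contacts `edge_jaccard` from [edge_loyalty()] plus the
#'   per-pair median/quartiles/n of node loyalty) and `overall` (list with
#'   `median`, `q1`, `q3`, `n` for the pooled node values and
#'   `edge_median`, `edge_q1`, `edge_q3` over the pair-level values).
#' @export
loyalty_series <- function(networks, mode = "union",
                           absent = c("zero", "drop"),
                           pooling = c("nodes", "pair_medians")) {
  absent <- match.arg(absent)
  pooling <- match.arg(pooling)
  if (length(networks) < 2)
    stop("need at least two monthly networks for a loyalty series")
  months <- names(networks)
  per_node <- dplyr::bind_rows(lapply(seq_len(length(networks) - 1),
                                      function(i) {
    g1 <- networks[[i]]
    g2 <- networks[[i + 1]]
    nodes <- if (absent == "drop") {
      intersect(igraph::V(g1)$name, igraph::V(g2)$name)
    } else {
      union(igraph::V(g1)$name, igraph::V(g2)$name)
    }
    vals <- vapply(nodes, function(v) node_loyalty(g1, g2, v, mode),
                   numeric(1))
    tibble::tibble(month_t = months[i], month_t1 = months[i + 1],
                   node = nodes, loyalty = unname(vals))
  }))
  per_node <- per_node[!is.na(per_node$loyalty), , drop = FALSE]
  pair_idx <- seq_len(length(networks) - 1)
  per_pair <- tibble::tibble(
    month_t = months[pair_idx], month_t1 = months[pair_idx + 1],
    edge_jaccard = vapply(pair_idx, function(i)
      edge_loyalty(networks[[i]], networks[[i + 1]]), numeric(1))) |>
    dplyr::left_join(
      per_node |>
        dplyr::summarise(
          median = stats::median(.data$loyalty),
          q1 = stats::quantile(.data$loyalty, 0.25, names = FALSE),
          q3 = stats::quantile(.data$loyalty, 0.75, names = FALSE),
          n = dplyr::n(),
          .by = c("month_t", "month_t1")),
      by = c("month_t", "month_t1"))
  pooled <- if (pooling == "nodes") per_node$loyalty else per_pair$median
  overall <- list(median = stats::median(pooled),
                  q1 = stats::quantile(pooled, 0.25, names = FALSE),
                  q3 = stats::quantile(pooled, 0.75, names = FALSE),
                  n = length(pooled),
                  edge_median = stats::median(per_pair$edge_jaccard,
                                              na.rm = TRUE),
                  edge_q1 = stats::quantile(per_pair$edge_jaccard, 0.25,
                                            na.rm = TRUE, names = FALSE),
                  edge_q3 = stats::quantile(per_pair$edge_jaccard, 0.75,
                                            na.rm = TRUE, names = FALSE))
  list(per_node = per_node, per_pair = per_pair, overall = overall)
}

#' Highly connected nodes of a monthly network
#'
#' Nodes are ranked by average degree (the mean of in- and out-degree) and
#' the top `ceiling(fraction * n)` are taken; every node tied with the
#' cut-off value is included, so the returned set can exceed that count.
#' The rule is deterministic and independent of node labelling.
#'
#' @param net An `igraph` directed network.
#' @param fraction Top fraction to take, in (0, 1\]; default 0.10.
#' @return Character vector of node names.
#' @export
top_connected <- function(net, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network has no highly connected nodes")
  avg <- (igraph::degree(net, mode = "in") +
            igraph::degree(net, mode = "out")) / 2
  k <- ceiling(fraction * n)
  cutoff <- sort(avg, decreasing = TRUE)[k]
  names(avg)[avg >= cutoff]
}

#' Similarity of highly connected node sets between months
#'
#' For each month pair, the Jaccard index of the two months' highly
#' connected node sets ([top_connected()]): the proportion of locations
#' that retained their highly connected position. The overall summary is
#' the median and quartiles over consecutive pairs.
#'
#' @param networks Ordered named list of monthly networks (at least 2).
#' @param fraction Top fraction, see [top_connected()].
#' @param pairs `"consecutive"` (default) or `"all"` unordered month pairs
#'   (for comparing months farther apart in time).
#' @return A list with `pairs` (tibble: `month_t`, `month_t1`, `lag`,
#'   `jaccard`, `n_top_t`, `n_top_t1`) and `overall` (median/quartiles over
#'   consecutive pairs).
#' @export
similarity_series <- function(networks, fraction = 0.10,
                              pairs = c("consecutive", "all")) {
  pairs <- match.arg(pairs)
  if (length(networks) < 2)
    stop("need at least two monthly networks for a similarity series")
  months <- names(networks)
  tops <- lapply(networks, top_connected, fraction = fraction)
  idx <- if (pairs == "consecutive") {
    cbind(seq_len(length(networks) - 1), seq_len(length(networks) - 1) + 1)
  } else {
    t(utils::combn(length(networks), 2))
  }
  tab <- tibble::tibble(
    month_t = months[idx[, 1]], month_t1 = months[idx[, 2]],
    lag = idx[, 2] - idx[, 1],
    jaccard = vapply(seq_len(nrow(idx)),
                     function(i) jaccard(tops[[idx[i, 1]]], tops[[idx[i, 2]]]),
                     numeric(1)),
    n_top_t = lengths(tops)[idx[, 1]],
    n_top_t1 = lengths(tops)[idx[, 2]])
  consec <- tab$jaccard[tab$lag == 1]
  overall <- list(median = stats::median(consec),
                  q1 = stats::quantile(consec, 0.25, names = FALSE),
                  q3 = stats::quantile(consec, 0.75, names = FALSE),
                  n = length(consec))
  list(pairs = tab, overall = overall)
}
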