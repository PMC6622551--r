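#' Edge reciprocity of a directed network
#'
#' The default variant is the edge-wise proportion of edges whose reverse
#' edge is present in the same network (1 means every movement between two
#' locations was matched by a movement back). The `"dyad"` variant is the
#' classical dyadic ratio (mutual dyads over connected dyads), provided for
#' comparison.
#'
#' @param net An `igraph` directed network.
#' @param variant `"edge"` (default) or `"dyad"`.
#' @return A proportion in \[0, 1\], or `NA` for an edgeless network.
#' @export
net_reciprocity <- function(net, variant = c("edge", "dyad")) {
  variant <- match.arg(variant)
  if (igraph::ecount(net) == 0) return(NA_real_)
  igraph::reciprocity(net, mode = if (variant == "edge") "default" else "ratio")
}

#' Nominal (categorical) assortativity of a directed network
#'
#' Newman's assortativity coefficient on the directed mixing matrix `e`
#' (fraction of edges running from category i to category j):
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` with `a`, `b`
#' the row and column sums. 1 means edges only join like categories, and
#' negative values mean unlike categories are preferentially joined.
#'
#' @param net An `igraph` directed network.
#' @param attribute Name of the vertex attribute holding the category.
#' @return Coefficient in \[-1, 1\]; `NA` when only one category is present
#'   (the coefficient is undefined, not zero).
#' @export
assortativity_nominal_attr <- function(net, attribute) {
  vals <- igraph::vertex_attr(net, attribute)
  if (is.null(vals)) stop("vertex attribute not present: ", attribute)
  if (anyNA(vals)) stop("vertex attribute has missing values: ", attribute)
  if (length(unique(vals)) < 2 || igraph::ecount(net) == 0) return(NA_real_)
  r <- igraph::assortativity_nominal(net, factor(vals), directed = TRUE)
  if (is.nan(r)) NA_real_ else r
}

#' Degree assortativity of a directed network
#'
#' Pearson correlation, across directed edges, of a degree value at the
#' source with a degree value at the target. The default convention pairs
#' the source's out-degree with the target's in-degree, using raw degrees.
#' The `"total"` convention uses total degree at both ends, and
#' `excess = TRUE` subtracts one from each degree (Newman's remaining-degree
#' variant); all are exposed because published tables rarely state which
#' convention produced them.
#'
#' @param net An `igraph` directed network.
#' @param convention `"out_in"` (default) or `"total"`.
#' @param excess Use excess (degree minus one) instead of raw degrees.
#' @return Coefficient in \[-1, 1\]; `NA` when fewer than two edges or zero
#'   degree variance at either end.
#' @export
assortativity_degree_net <- function(net, convention = c("out_in", "total"),
                                     excess = FALSE) {
  convention <- match.arg(convention)
  el <- igraph::as_edgelist(net)
  if (nrow(el) < 2) return(NA_real_)
  if (convention == "out_in") {
    x <- igraph::degree(net, mode = "out")[el[, 1]]
    y <- igraph::degree(net, mode = "in")[el[, 2]]
  } else {
    x <- igraph::degree(net, mode = "all")[el[, 1]]
    y <- igraph::degree(net, mode = "all")[el[, 2]]
  }
  if (excess) {
    x <- x - 1
    y <- y - 1
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  unname(stats::cor(x, y))
}

#' Giant strong component of a directed network
#'
#' The largest set of locations mutually reachable through directed paths —
#' an upper bound on how far an outbreak could spread and return. Ties
#' between equal-sized largest components are broken arbitrarily; only the
#' size is meaningful in that case.
#'
#' @param net An `igraph` directed network.
#' @return Character vector of node names in the largest strongly connected
#'   component (empty for an empty network).
#' @export
giant_strong_component <- function(net) {
  if (igraph::vcount(net) == 0) return(character())
  comp <- igraph::components(net, mode = "strong")
  igraph::V(net)$name[comp$membership == which.max(comp$csize)]
}

#' In- and out-degree summaries over the nodes of a network
#'
#' @param net An `igraph` directed network.
#' @return A list with `in_median`, `in_min`, `in_max`, `out_median`,
#'   `out_min`, `out_max` (all `NA` for an empty network).
#' @export
degree_summary <- function(net) {
  if (igraph::vcount(net) == 0)
    return(list(in_median = NA_real_, in_min = NA_integer_,
                in_max = NA_integer_, out_median = NA_real_,
                out_min = NA_integer_, out_max = NA_integer_))
  din <- igraph::degree(net, mode = "in")
  dout <- igraph::degree(net, mode = "out")
  list(in_median = stats::median(din), in_min = min(din), in_max = max(din),
       out_median = stats::median(dout), out_min = min(dout),
       out_max = max(dout))
}

#' Static measure table for a list of monthly networks
#'
#' Assembles, one row per month: node and edge counts, reciprocity,
#' assortativity by degree, location type and discipline, giant strong
#' component size, and degree summaries. Coefficients that are undefined
#' for a month (single category, zero degree variance, no edges) are
#' reported as `NA` rather than fabricated as zero.
#'
#' @param networks Named list of monthly networks from
#'   [build_monthly_networks()].
#' @param reciprocity_variant Passed to [net_reciprocity()].
#' @param degree_convention,degree_excess Passed to
#'   [assortativity_degree_net()].
#' @return A tibble with one row per month.
#' @export
measure_table <- function(networks, reciprocity_variant = "edge",
                          degree_convention = "out_in",
                          degree_excess = FALSE) {
  safe_nominal <- function(g, attr) {
    vals <- igraph::vertex_attr(g, attr)
    if (is.null(vals) || anyNA(vals)) return(NA_real_)
    assortativity_nominal_attr(g, attr)
  }
  rows <- lapply(networks, function(g) {
    ds <- degree_summary(g)
    tibble::tibble(
      month = igraph::graph_attr(g, "month"),
      n_nodes = igraph::vcount(g),
      n_edges = igraph::ecount(g),
      reciprocity = net_reciprocity(g, reciprocity_variant),
      assort_degree = assortativity_degree_net(g, degree_convention,
                                               degree_excess),
      assort_type = safe_nominal(g, "type"),
      assort_discipline = safe_nominal(g, "discipline"),
      gsc_size = length(giant_strong_component(g)),
      in_degree_median = ds$in_median,
      in_degree_min = ds$in_min, in_degree_max = ds$in_max,
      out_degree_median = ds$out_median,
      out_degree_min = ds$out_min, out_degree_max = ds$out_max)
  })
  dplyr::bind_rows(rows)
}
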