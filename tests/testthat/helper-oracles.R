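# Brute-force oracles computed straight from an edge list (a 2-column
# character matrix), independent of the igraph-based implementation.

el_nodes <- function(el) sort(unique(c(el[, 1], el[, 2])))

oracle_reciprocity <- function(el) {
  if (nrow(el) == 0) return(NA_real_)
  keys <- paste(el[, 1], el[, 2])
  rev_keys <- paste(el[, 2], el[, 1])
  mean(rev_keys %in% keys)
}

oracle_assort_nominal <- function(el, types) {
  if (nrow(el) == 0 || length(unique(types)) < 2) return(NA_real_)
  cats <- sort(unique(types))
  e <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (k in seq_len(nrow(el)))
    e[types[[el[k, 1]]], types[[el[k, 2]]]] <-
      e[types[[el[k, 1]]], types[[el[k, 2]]]] + 1
  e <- e / sum(e)
  ab <- sum(rowSums(e) * colSums(e))
  if (abs(1 - ab) < 1e-12) return(NA_real_)
  (sum(diag(e)) - ab) / (1 - ab)
}

oracle_degrees <- function(el) {
  nodes <- el_nodes(el)
  list(nodes = nodes,
       din = vapply(nodes, function(v) sum(el[, 2] == v), numeric(1)),
       dout = vapply(nodes, function(v) sum(el[, 1] == v), numeric(1)))
}

oracle_assort_degree <- function(el) {
  if (nrow(el) < 2) return(NA_real_)
  d <- oracle_degrees(el)
  x <- d$dout[el[, 1]]
  y <- d$din[el[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  unname(cor(x, y))
}

# largest strongly connected component via boolean reachability closure
oracle_gsc_size <- function(el) {
  nodes <- el_nodes(el)
  n <- length(nodes)
  if (n == 0) return(0L)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[el] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  max(rowSums(mutual))
}

oracle_neighbours <- function(el, node) {
  setdiff(unique(c(el[el[, 1] == node, 2], el[el[, 2] == node, 1])), node)
}

oracle_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) NA_real_ else length(intersect(a, b)) / u
}

oracle_top_set <- function(el, fraction = 0.1) {
  d <- oracle_degrees(el)
  avg <- (d$din + d$dout) / 2
  k <- ceiling(fraction * length(avg))
  cutoff <- sort(avg, decreasing = TRUE)[k]
  d$nodes[avg >= cutoff]
}

# random directed graph as an edge-list matrix (possibly empty)
random_el <- function(n, p) {
  nodes <- paste0("v", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  as.matrix(pairs[keep, , drop = FALSE])
}

# the i-th of the 64 possible digraphs on 3 labelled nodes
enumerate_el3 <- function(mask) {
  nodes <- c("a", "b", "c")
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- bitwAnd(mask, 2^(0:5)) > 0
  as.matrix(pairs[keep, , drop = FALSE])
}

graph_from_el <- function(el, types = NULL) {
  g <- igraph::graph_from_data_frame(as.data.frame(el), directed = TRUE)
  if (!is.null(types)) igraph::V(g)$type <- unname(types[igraph::V(g)$name])
  g
}
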