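#' Undirected weighted network
#'
#' The evolving state of the simulator and the input of every analysis
#' routine: a simple undirected graph on nodes `1..n_nodes` whose edges carry
#' strictly positive weights. Edges are stored canonically as a data frame
#' with columns `i < j` and `w`, sorted by `(i, j)`.
#'
#' @param edges Data frame (or list) with integer columns `i`, `j` and a
#'   numeric column `w`; each row one undirected edge.
#' @param n_nodes Number of nodes; must cover all edge endpoints.
#' @return An object of class `weighted_network`.
#' @examples
#' net <- weighted_network(data.frame(i = c(1, 1), j = c(2, 3), w = 1), 4)
#' degrees(net)
#' @export
weighted_network <- function(edges, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1, !is.na(n_nodes), n_nodes >= 1)
  i <- as.integer(edges$i); j <- as.integer(edges$j); w <- as.numeric(edges$w)
  if (length(i) != length(j) || length(i) != length(w))
    stop("edge columns 'i', 'j', 'w' must have equal length", call. = FALSE)
  if (length(i)) {
    if (anyNA(i) || anyNA(j) || anyNA(w))
      stop("edge list contains missing values", call. = FALSE)
    if (any(i < 1L) || any(j < 1L) || any(i > n_nodes) || any(j > n_nodes))
      stop("edge endpoints outside 1..n_nodes", call. = FALSE)
    if (any(i == j)) stop("self-loops are not allowed", call. = FALSE)
    if (any(w <= 0)) stop("edge weights must be strictly positive",
                          call. = FALSE)
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    o <- order(i, j)
    i <- i[o]; j <- j[o]; w <- w[o]
    if (anyDuplicated(cbind(i, j)))
      stop("duplicate edges are not allowed", call. = FALSE)
  }
  structure(list(n_nodes = n_nodes,
                 edges = data.frame(i = i, j = j, w = w)),
            class = "weighted_network")
}

#' Edgeless network of `n` nodes
#' @param n Number of nodes.
#' @return A `weighted_network` with no edges.
#' @export
empty_network <- function(n) {
  weighted_network(data.frame(i = integer(), j = integer(), w = numeric()), n)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges, <k> = %.3f\n",
              x$n_nodes, nrow(x$edges), average_degree(x)))
  invisible(x)
}

#' Number of edges
#' @param net A `weighted_network`.
#' @return Integer edge count.
#' @export
edge_count <- function(net) nrow(net$edges)

#' Node degrees
#' @param net A `weighted_network`.
#' @return Integer vector of length `n_nodes`.
#' @export
degrees <- function(net) {
  tabulate(c(net$edges$i, net$edges$j), nbins = net$n_nodes)
}

#' Node strengths (sum of incident tie weights)
#' @param net A `weighted_network`.
#' @return Numeric vector of length `n_nodes`.
#' @export
strengths <- function(net) {
  s <- numeric(net$n_nodes)
  if (nrow(net$edges)) {
    agg <- rowsum(c(net$edges$w, net$edges$w), c(net$edges$i, net$edges$j))
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  s
}

#' Mean degree 2m/N
#' @param net A `weighted_network`.
#' @return Average degree.
#' @export
average_degree <- function(net) 2 * nrow(net$edges) / net$n_nodes

#' Weight of one edge
#' @param net A `weighted_network`.
#' @param i,j Endpoints.
#' @return The weight, or `NA` if the edge is absent.
#' @export
get_weight <- function(net, i, j) {
  a <- min(i, j); b <- max(i, j)
  hit <- net$edges$i == a & net$edges$j == b
  if (any(hit)) net$edges$w[hit][1] else NA_real_
}

# sparse adjacency matrix (Matrix package); binary unless weighted = TRUE
adjacency_sparse <- function(net, weighted = FALSE) {
  e <- net$edges
  x <- if (weighted) e$w else rep(1, nrow(e))
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = c(x, x),
                       dims = c(net$n_nodes, net$n_nodes))
}

# neighbour list (list of integer vectors)
neighbor_list <- function(net) {
  nb <- vector("list", net$n_nodes)
  e <- net$edges
  if (nrow(e)) {
    from <- c(e$i, e$j); to <- c(e$j, e$i)
    o <- order(from, to)
    nb_split <- split(to[o], factor(from[o], levels = seq_len(net$n_nodes)))
    nb <- lapply(nb_split, as.integer)
  } else {
    nb <- rep(list(integer()), net$n_nodes)
  }
  nb
}

net_from_cpp <- function(lst, n_nodes) {
  weighted_network(data.frame(i = lst$i, j = lst$j, w = lst$w), n_nodes)
}

edge_vectors <- function(net) {
  list(i = as.integer(net$edges$i), j = as.integer(net$edges$j),
       w = as.numeric(net$edges$w))
}
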