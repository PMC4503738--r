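#' Distribution estimates and binned profiles
#'
#' `dist_estimate` holds a normalized probability mass per bin (discrete
#' values, or linear/logarithmic bins); `binned_profile` holds per-bin means
#' of a quantity with standard errors and counts. Both are thin data-frame
#' wrappers used by every distribution / profile routine.
#'
#' @param x Bin values (discrete) or bin centers.
#' @param mass Probability mass per bin; must sum to 1 over the observed
#'   support (up to 1e-9).
#' @param count Sample count per bin.
#' @param breaks Bin edges (NULL for discrete estimates).
#' @param mode One of `"discrete"`, `"linear"`, `"log"`.
#' @return An object of class `dist_estimate`.
#' @export
dist_estimate <- function(x, mass, count, breaks = NULL, mode = "discrete") {
  stopifnot(length(x) == length(mass), all(mass >= 0),
            abs(sum(mass) - 1) < 1e-9)
  if (!is.null(breaks) && any(diff(breaks) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  structure(list(x = x, mass = mass, count = count, breaks = breaks,
                 mode = mode),
            class = "dist_estimate")
}

#' @export
print.dist_estimate <- function(x, ...) {
  cat(sprintf("dist_estimate (%s), %d bins, n = %d\n", x$mode, length(x$x),
              sum(x$count)))
  invisible(x)
}

#' @export
as.data.frame.dist_estimate <- function(x, ...) {
  data.frame(x = x$x, mass = x$mass, count = x$count)
}

binned_profile <- function(x, mean, se, count) {
  structure(data.frame(x = x, mean = mean, se = se, count = count),
            class = c("binned_profile", "data.frame"))
}

# group values by an integer class (degree), returning a binned_profile
profile_by_class <- function(cls, values) {
  ks <- sort(unique(cls))
  mu <- vapply(ks, function(k) mean(values[cls == k]), numeric(1))
  se <- vapply(ks, function(k) {
    v <- values[cls == k]
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  ct <- vapply(ks, function(k) sum(cls == k), integer(1))
  binned_profile(ks, mu, se, ct)
}

# log-spaced breaks covering x > 0; multiplicative width `factor`
log_breaks <- function(x, factor = 10^0.1) {
  lo <- min(x)
  k <- max(1L, ceiling(log(max(x) / lo) / log(factor)))
  br <- lo * factor^(0:k)
  br[length(br)] <- br[length(br)] * (1 + 1e-12)  # include max(x)
  br
}

log_binned_dist <- function(x, factor = 10^0.1) {
  br <- log_breaks(x, factor)
  cut_idx <- findInterval(x, br, rightmost.closed = TRUE)
  ct <- tabulate(cut_idx, nbins = length(br) - 1L)
  centers <- sqrt(br[-length(br)] * br[-1])
  keep <- ct > 0
  dist_estimate(centers[keep], ct[keep] / length(x), ct[keep], breaks = br,
                mode = "log")
}

#' Degree distribution P(k)
#'
#' Empirical distribution over all nodes, including isolated ones (k = 0).
#'
#' @param net A [weighted_network()].
#' @return A [dist_estimate()] over the observed degrees.
#' @export
degree_distribution <- function(net) {
  k <- degrees(net)
  ct <- tabulate(k + 1L, nbins = max(k) + 1L)
  keep <- ct > 0
  vals <- (0:max(k))[keep]
  dist_estimate(vals, ct[keep] / net$n_nodes, ct[keep], mode = "discrete")
}

#' Node strength distribution P(s)
#'
#' Logarithmically binned over s > 0; the fraction of zero-strength
#' (isolated) nodes is reported separately in the `zero_fraction` attribute
#' since log bins cannot hold zero. Masses sum to 1 over the positive
#' support.
#'
#' @param net A [weighted_network()].
#' @param bin_factor Multiplicative bin width (default `10^0.1`).
#' @return A [dist_estimate()] with attribute `zero_fraction`.
#' @export
strength_distribution <- function(net, bin_factor = 10^0.1) {
  s <- strengths(net)
  pos <- s[s > 0]
  if (!length(pos)) stop("all nodes are isolated", call. = FALSE)
  d <- log_binned_dist(pos, bin_factor)
  attr(d, "zero_fraction") <- mean(s == 0)
  d
}

#' Link weight distribution P(w)
#'
#' Logarithmically binned over the edge weights; optionally fits a
#' maximum-likelihood power-law exponent over a caller-given window
#' (see [fit_power_law()]), attached as attribute `fit`.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param bin_factor Multiplicative bin width.
#' @param fit_range Optional `c(wmin, wmax)` window for the exponent fit.
#' @return A [dist_estimate()], with attribute `fit` when requested.
#' @export
weight_distribution <- function(net, bin_factor = 10^0.1, fit_range = NULL) {
  if (!nrow(net$edges)) stop("network has no edges", call. = FALSE)
  d <- log_binned_dist(net$edges$w, bin_factor)
  if (!is.null(fit_range))
    attr(d, "fit") <- fit_power_law(net$edges$w, fit_range[1], fit_range[2])
  d
}

#' Maximum-likelihood power-law exponent on a window
#'
#' Fits a continuous truncated power law `p(x) ~ x^(-alpha)` to the sample
#' restricted to `[wmin, wmax]`, by numerical maximum likelihood (the window
#' is caller-specified; there is no automatic lower-cutoff selection). The
#' reported `exponent` is `-alpha`. The standard error comes from the
#' observed information (numerical second derivative).
#'
#' @param x Numeric sample.
#' @param wmin,wmax Fit window; `0 < wmin < wmax`.
#' @return List with `exponent`, `alpha`, `se`, `n`, `wmin`, `wmax`; class
#'   `powerlaw_fit`.
#' @export
fit_power_law <- function(x, wmin, wmax) {
  stopifnot(wmin > 0, wmax > wmin)
  x <- x[x >= wmin & x <= wmax]
  n <- length(x)
  if (n < 10) stop("too few points in the fit window", call. = FALSE)
  if (max(x) / min(x) < 1 + 1e-9)
    stop("degenerate support: all values in the window are equal",
         call. = FALSE)
  logZ <- function(alpha) {
    if (abs(alpha - 1) < 1e-8) return(log(log(wmax / wmin)))
    om <- 1 - alpha
    # log((wmax^om - wmin^om)/om), stable for either sign of om
    log(abs((wmax^om - wmin^om) / om))
  }
  sl <- sum(log(x))
  nll <- function(alpha) alpha * sl + n * logZ(alpha)
  opt <- stats::optimize(nll, interval = c(-2, 10), tol = 1e-8)
  a <- opt$minimum
  h <- 1e-4
  d2 <- (nll(a + h) - 2 * nll(a) + nll(a - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  structure(list(exponent = -a, alpha = a, se = se, n = n,
                 wmin = wmin, wmax = wmax),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: exponent %.3f (se %.3f), n = %d on [%g, %g]\n",
              x$exponent, x$se, x$n, x$wmin, x$wmax))
  invisible(x)
}

#' Neighbourhood overlap of a tie
#'
#' Fraction of common neighbours of the connected pair (i, j) among their
#' combined other neighbours:
#' `O_ij = n_ij / ((k_i - 1) + (k_j - 1) - n_ij)`.
#' Returns 0 when the denominator is 0 (an isolated dyad). Errors if (i, j)
#' is not an edge.
#'
#' @param net A [weighted_network()].
#' @param i,j Endpoints of an existing edge.
#' @return Overlap in `[0, 1]`.
#' @export
overlap <- function(net, i, j) {
  if (is.na(get_weight(net, i, j)))
    stop(sprintf("(%d, %d) is not an edge", i, j), call. = FALSE)
  nb <- neighbor_list(net)
  nij <- length(intersect(nb[[i]], nb[[j]]))
  ki <- length(nb[[i]]); kj <- length(nb[[j]])
  den <- (ki - 1) + (kj - 1) - nij
  if (den <= 0) 0 else nij / den
}

#' Overlap of every edge
#'
#' Vectorized [overlap()] over the whole edge list.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @return Numeric vector aligned with `net$edges`.
#' @export
edge_overlaps <- function(net) {
  if (!nrow(net$edges)) return(numeric())
  A <- adjacency_sparse(net)
  k <- degrees(net)
  e <- net$edges
  nij <- as.numeric((A %*% A)[cbind(e$i, e$j)])
  den <- (k[e$i] - 1) + (k[e$j] - 1) - nij
  ifelse(den <= 0, 0, nij / den)
}

#' Overlap as a function of link weight
#'
#' Mean overlap over logarithmically spaced weight bins with standard
#' errors. An increasing profile is the weak-tie (Granovetterian)
#' signature.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param n_bins Number of log-spaced weight bins.
#' @return A `binned_profile` (empty bins dropped).
#' @export
overlap_vs_weight <- function(net, n_bins = 25) {
  if (!nrow(net$edges)) stop("network has no edges", call. = FALSE)
  o <- edge_overlaps(net)
  w <- net$edges$w
  lo <- min(w); hi <- max(w)
  if (hi / lo < 1 + 1e-12) {   # single weight value: one bin
    return(binned_profile(lo, mean(o),
                          if (length(o) < 2) 0
                          else stats::sd(o) / sqrt(length(o)), length(o)))
  }
  br <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  br[length(br)] <- br[length(br)] * (1 + 1e-12)
  idx <- findInterval(w, br, rightmost.closed = TRUE)
  centers <- sqrt(br[-length(br)] * br[-1])
  keep <- sort(unique(idx))
  mu <- vapply(keep, function(b) mean(o[idx == b]), numeric(1))
  se <- vapply(keep, function(b) {
    v <- o[idx == b]
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  ct <- vapply(keep, function(b) sum(idx == b), integer(1))
  binned_profile(centers[keep], mu, se, ct)
}

triangle_counts <- function(net) {
  if (!nrow(net$edges)) return(numeric(net$n_nodes))
  A <- adjacency_sparse(net)
  as.numeric(Matrix::rowSums((A %*% A) * A)) / 2
}

#' Clustering coefficients
#'
#' `local_clustering` is `triangles(i) / (k_i (k_i - 1) / 2)`, defined as 0
#' for `k_i < 2`. `average_clustering` averages the local value over all
#' nodes (the model's reported C); `transitivity_global`
#' (3 x triangles / connected triples) is exposed for cross-checking.
#' Weights are ignored throughout.
#'
#' @param net A [weighted_network()].
#' @param i Optional single node; default all nodes.
#' @return `local_clustering`: numeric vector (or scalar); the others:
#'   scalars.
#' @export
local_clustering <- function(net, i = NULL) {
  k <- degrees(net)
  tri <- triangle_counts(net)
  c_all <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  if (is.null(i)) c_all else c_all[i]
}

#' @rdname local_clustering
#' @export
average_clustering <- function(net) mean(local_clustering(net))

#' @rdname local_clustering
#' @export
transitivity_global <- function(net) {
  k <- degrees(net)
  triads <- sum(k * (k - 1) / 2)
  if (triads == 0) return(0)
  # per-node triangle counts sum to 3 * (number of triangles)
  sum(triangle_counts(net)) / triads
}

#' Local clustering as a function of degree
#' @param net A [weighted_network()].
#' @return A `binned_profile` over degree classes (all nodes).
#' @export
clustering_vs_degree <- function(net) {
  profile_by_class(degrees(net), local_clustering(net))
}

#' Average neighbour degree as a function of degree
#'
#' For each degree class k, the mean over nodes of that degree of the
#' average degree of their neighbours. An increasing profile indicates
#' assortative mixing.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @return A `binned_profile` over degree classes k >= 1.
#' @export
knn_vs_degree <- function(net) {
  if (!nrow(net$edges)) stop("network has no edges", call. = FALSE)
  A <- adjacency_sparse(net)
  k <- degrees(net)
  keep <- k > 0
  knn <- as.numeric(A %*% k)[keep] / k[keep]
  profile_by_class(k[keep], knn)
}

#' Node strength as a function of degree
#' @param net A [weighted_network()].
#' @return A `binned_profile` of mean strength per degree class (all nodes).
#' @export
strength_vs_degree <- function(net) {
  profile_by_class(degrees(net), strengths(net))
}
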