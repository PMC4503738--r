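#' Link percolation curve
#'
#' Removes edges one by one in ascending or descending order of weight
#' (ties randomly permuted per shuffle, seeded) and records the relative
#' size of the largest connected component, R_LCC, after each removal, via
#' incremental union-find connectivity on the reversed insertion sequence.
#' The size of the second-largest component is tracked alongside for
#' threshold estimation. Curves are averaged over `n_shuffles` tie
#' permutations.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param order `"ascending"` (weak ties first) or `"descending"`.
#' @param n_shuffles Number of tie permutations averaged (default 10).
#' @param seed Integer seed.
#' @return An object of class `percolation_curve`: data frame columns `f`
#'   (removed fraction, 0..1), `rlcc`, `s2` (second-largest / N), plus
#'   attributes `order` and `n_shuffles`.
#' @examples
#' net <- make_fixture("bridged_cliques", sizes = c(5, 5))
#' curve <- link_percolation_curve(net, "ascending")
#' curve$rlcc[2]  # after removing the (weakest) bridge: 0.5
#' @export
link_percolation_curve <- function(net, order = c("ascending", "descending"),
                                   n_shuffles = 10, seed = 1) {
  order <- match.arg(order)
  m <- nrow(net$edges)
  if (!m) stop("network has no edges", call. = FALSE)
  ev <- edge_vectors(net)
  res <- cpp_percolation_curve(net$n_nodes, ev$i, ev$j, ev$w,
                               order == "descending", as.integer(n_shuffles),
                               seed)
  structure(data.frame(f = (0:m) / m, rlcc = res$rlcc, s2 = res$s2),
            order = order, n_shuffles = n_shuffles,
            class = c("percolation_curve", "data.frame"))
}

#' Percolation threshold of a curve
#'
#' Default criterion: the removed fraction at the peak of the
#' second-largest component size (the standard transition locator).
#' Alternative: the first removed fraction with `R_LCC < 0.01`. A curve
#' with no discernible transition (the second-largest component never
#' exceeds a single node, or the criterion level is never reached) is
#' flagged via the `flat` attribute.
#'
#' @param curve A [link_percolation_curve()] result.
#' @param criterion `"second_largest_peak"` or `"rlcc_small"`.
#' @return The threshold fraction in `[0, 1]`, with attributes `criterion`
#'   and `flat`.
#' @export
percolation_threshold <- function(curve,
                                  criterion = c("second_largest_peak",
                                                "rlcc_small")) {
  criterion <- match.arg(criterion)
  n_implied <- 1 / min(curve$rlcc[curve$rlcc > 0])
  if (criterion == "second_largest_peak") {
    fc <- curve$f[which.max(curve$s2)]
    flat <- max(curve$s2) <= 1.5 / n_implied
  } else {
    hit <- which(curve$rlcc < 0.01)
    flat <- !length(hit)
    fc <- if (flat) 1 else curve$f[hit[1]]
  }
  structure(fc, criterion = criterion, flat = flat)
}

#' Weak-tie bridging gap between percolation thresholds
#'
#' `delta_fc = f_c(descending) - f_c(ascending)`. A positive gap means the
#' network fragments earlier when weak ties are removed first — the
#' weak-tie (Granovetterian) signature.
#'
#' @inheritParams link_percolation_curve
#' @inheritParams percolation_threshold
#' @return List with `delta_fc`, `fc_ascending`, `fc_descending`, and both
#'   curves.
#' @export
delta_fc <- function(net, n_shuffles = 10, seed = 1,
                     criterion = c("second_largest_peak", "rlcc_small")) {
  criterion <- match.arg(criterion)
  asc <- link_percolation_curve(net, "ascending", n_shuffles, seed)
  desc <- link_percolation_curve(net, "descending", n_shuffles, seed + 1)
  fa <- percolation_threshold(asc, criterion)
  fd <- percolation_threshold(desc, criterion)
  list(delta_fc = as.numeric(fd) - as.numeric(fa),
       fc_ascending = fa, fc_descending = fd,
       ascending = asc, descending = desc)
}
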