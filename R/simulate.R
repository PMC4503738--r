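#' Run the tie-formation model
#'
#' Starts from an edgeless network of `n_nodes` nodes and applies
#' `params$steps` time steps. Each step applies, in order: a local-attachment
#' sweep (every node, in a fresh random permutation, attempts a weighted
#' two-step walk closing a triad), a global-attachment sweep (isolated nodes
#' always link; others with probability `p_r`, to a uniform non-neighbour),
#' and the termination sweep of the chosen mechanism. Identical parameters and
#' seed give bit-identical results.
#'
#' @param params A [model_params()] object.
#' @param record_timeseries If `TRUE`, record the mean degree after every
#'   step (length `steps + 1`, including the initial state).
#' @param verbose Log per-1000-step progress to standard error.
#' @return An object of class `run_result`: a list with elements `network`
#'   (the final [weighted_network()]), `params`, `seed`, and `k_mean` (the
#'   time series, or `NULL`).
#' @examples
#' p <- model_params(50, "LD", p_ld = 0.01, p_r = 0.01, steps = 20, seed = 1)
#' res <- run_simulation(p)
#' average_degree(res$network)
#' @export
run_simulation <- function(params, record_timeseries = FALSE,
                           verbose = FALSE) {
  validate_params(params)
  evolve(empty_network(params$n_nodes), params, steps = params$steps,
         seed = params$seed, record_timeseries = record_timeseries,
         verbose = verbose)
}

#' Evolve an existing network
#'
#' Applies `steps` model time steps to `net` with the mechanism and rates in
#' `params`. Used by [run_simulation()] (from the edgeless state) and
#' directly for controlled experiments such as an isolated clique under
#' local attachment and aging.
#'
#' @param net Initial [weighted_network()]; `net$n_nodes` must equal
#'   `params$n_nodes`.
#' @inheritParams run_simulation
#' @param steps Number of steps to apply.
#' @param seed Seed of the run's random stream.
#' @return A `run_result` (see [run_simulation()]).
#' @export
evolve <- function(net, params, steps = params$steps, seed = params$seed,
                   record_timeseries = FALSE, verbose = FALSE) {
  validate_params(params)
  stopifnot(net$n_nodes == params$n_nodes)
  ev <- edge_vectors(net)
  m <- params
  out <- cpp_evolve(net$n_nodes, ev$i, ev$j, ev$w, as.integer(steps),
                    m$p_delta, m$p_r, m$w0, m$delta,
                    mechanism_code(m$mechanism),
                    if (is.null(m$p_nd)) 0 else m$p_nd,
                    if (is.null(m$p_ld)) 0 else m$p_ld,
                    if (is.null(m$aging_factor)) 0.5 else m$aging_factor,
                    if (is.null(m$w_th)) 0 else m$w_th,
                    seed, record_timeseries, verbose)
  structure(list(network = net_from_cpp(out, net$n_nodes), params = params,
                 seed = seed,
                 k_mean = if (record_timeseries) out$k_mean else NULL),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result (%s, seed %d): ", x$params$mechanism, x$seed))
  print(x$network)
  invisible(x)
}

#' One model time step
#'
#' Local attachment, then global attachment, then the termination sweep.
#'
#' @inheritParams evolve
#' @return The successor [weighted_network()].
#' @export
step_network <- function(net, params, seed = params$seed) {
  evolve(net, params, steps = 1L, seed = seed)$network
}

#' Individual sweeps
#'
#' The three phases of a time step, exposed separately for testing and for
#' controlled experiments. `la_sweep` visits every node in a seeded random
#' permutation with immediate updates; `la_event` performs the two-step walk
#' for a single initiating node. `ga_sweep` links isolated nodes always and
#' others with probability `p_r`. `nd_sweep`, `ld_sweep` and `aging_sweep`
#' are the termination mechanisms; `aging_sweep` is deterministic.
#'
#' @inheritParams evolve
#' @param node Initiating node for `la_event`.
#' @return The updated [weighted_network()].
#' @name sweeps
NULL

#' @rdname sweeps
#' @export
la_sweep <- function(net, params, seed = params$seed) {
  validate_params(params)
  ev <- edge_vectors(net)
  net_from_cpp(cpp_la_sweep(net$n_nodes, ev$i, ev$j, ev$w, params$p_delta,
                            params$w0, params$delta, seed), net$n_nodes)
}

#' @rdname sweeps
#' @export
la_event <- function(net, node, params, seed = params$seed) {
  validate_params(params)
  ev <- edge_vectors(net)
  net_from_cpp(cpp_la_event(net$n_nodes, ev$i, ev$j, ev$w, as.integer(node),
                            params$p_delta, params$w0, params$delta, seed),
               net$n_nodes)
}

#' @rdname sweeps
#' @export
ga_sweep <- function(net, params, seed = params$seed) {
  validate_params(params)
  ev <- edge_vectors(net)
  net_from_cpp(cpp_ga_sweep(net$n_nodes, ev$i, ev$j, ev$w, params$p_r,
                            params$w0, seed), net$n_nodes)
}

#' @rdname sweeps
#' @export
nd_sweep <- function(net, params, seed = params$seed) {
  stopifnot(identical(params$mechanism, "ND"))
  validate_params(params)
  ev <- edge_vectors(net)
  net_from_cpp(cpp_nd_sweep(net$n_nodes, ev$i, ev$j, ev$w, params$p_nd, seed),
               net$n_nodes)
}

#' @rdname sweeps
#' @export
ld_sweep <- function(net, params, seed = params$seed) {
  stopifnot(identical(params$mechanism, "LD"))
  validate_params(params)
  ev <- edge_vectors(net)
  net_from_cpp(cpp_ld_sweep(net$n_nodes, ev$i, ev$j, ev$w, params$p_ld, seed),
               net$n_nodes)
}

#' @rdname sweeps
#' @export
aging_sweep <- function(net, params) {
  stopifnot(identical(params$mechanism, "AGING"))
  validate_params(params)
  ev <- edge_vectors(net)
  net_from_cpp(cpp_aging_sweep(net$n_nodes, ev$i, ev$j, ev$w,
                               params$aging_factor, params$w_th),
               net$n_nodes)
}

#' Ensemble of independent runs
#'
#' Per-realization seeds are `base_seed + index - 1`, so an ensemble is fully
#' reproducible from `(params, base_seed)`.
#'
#' @inheritParams run_simulation
#' @param n_realizations Number of independent runs (>= 1).
#' @param base_seed Base seed; realization `r` uses `base_seed + r - 1`.
#' @return A list of `run_result` objects, class `run_ensemble`.
#' @export
run_ensemble <- function(params, n_realizations, base_seed = params$seed,
                         record_timeseries = FALSE, verbose = FALSE) {
  stopifnot(n_realizations >= 1)
  out <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    pr <- params
    pr$seed <- as.integer(base_seed + r - 1L)
    out[[r]] <- run_simulation(pr, record_timeseries = record_timeseries,
                               verbose = verbose)
  }
  structure(out, class = "run_ensemble")
}

#' Summarize an ensemble with a per-network statistic
#'
#' @param ensemble A `run_ensemble`.
#' @param stat Function mapping a [weighted_network()] to a scalar.
#' @return List with `values`, `mean`, and standard error `se` (over
#'   realizations).
#' @export
ensemble_stat <- function(ensemble, stat) {
  v <- vapply(ensemble, function(r) stat(r$network), numeric(1))
  list(values = v, mean = mean(v),
       se = stats::sd(v) / sqrt(length(v)))
}
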