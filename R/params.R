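#' Simulation parameters
#'
#' Bundle and validate all constants of the tie-formation model: network size,
#' the cyclic-closure (local attachment) probability `p_delta`, the
#' focal-closure (global attachment) probability `p_r`, the weight `w0` of a
#' newly created tie, the reinforcement increment `delta`, and the parameters
#' of the chosen termination mechanism.
#'
#' Termination mechanisms:
#' * `"ND"` (node deletion): each node loses all its ties with probability
#'   `p_nd` per step.
#' * `"LD"` (link deletion): each tie is removed with probability `p_ld` per
#'   step, independently of its weight.
#' * `"AGING"`: every weight is multiplied by `aging_factor` each step and
#'   ties whose weight falls below `w_th` are removed.
#'
#' Fields irrelevant to the chosen mechanism may be left `NULL`; validation
#' only requires the mechanism's own fields.
#'
#' @param n_nodes Number of nodes N (positive integer).
#' @param mechanism One of `"ND"`, `"LD"`, `"AGING"`.
#' @param p_delta Probability of creating the closing tie of a triad.
#' @param p_r Per-step probability of focal closure for a connected node
#'   (isolated nodes always link).
#' @param w0 Initial weight of a new tie (> 0).
#' @param delta Reinforcement increment added to the ties involved in a
#'   completed local-attachment walk (>= 0).
#' @param p_nd Node-deletion probability (ND only).
#' @param p_ld Link-deletion probability (LD only).
#' @param aging_factor Multiplicative decay factor f, strictly in (0,1)
#'   (AGING only).
#' @param w_th Removal threshold for aged weights (> 0, AGING only).
#' @param steps Number of time steps T (>= 0).
#' @param seed Integer seed for the run's random stream.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(200, "AGING", aging_factor = 0.9, w_th = 0.01,
#'                   p_r = 0.005, steps = 100)
#' @export
model_params <- function(n_nodes, mechanism = c("ND", "LD", "AGING"),
                         p_delta = 0.05, p_r = 0.0005, w0 = 1, delta = 1,
                         p_nd = NULL, p_ld = NULL, aging_factor = NULL,
                         w_th = NULL, steps = 25000, seed = 1L) {
  mechanism <- match.arg(mechanism)
  p <- structure(list(n_nodes = as.integer(n_nodes), mechanism = mechanism,
                      p_delta = p_delta, p_r = p_r, w0 = w0, delta = delta,
                      p_nd = p_nd, p_ld = p_ld, aging_factor = aging_factor,
                      w_th = w_th, steps = as.integer(steps),
                      seed = as.integer(seed)),
                 class = "model_params")
  validate_params(p)
  p
}

#' Validate a `model_params` object
#'
#' Checks ranges and that the chosen mechanism's own fields are set.
#'
#' @param p A `model_params` object.
#' @return `p`, invisibly; stops with an informative error otherwise.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  chk_prob <- function(x, nm) {
    if (is.null(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a probability in [0,1]", nm), call. = FALSE)
  }
  if (is.na(p$n_nodes) || p$n_nodes < 1)
    stop("'n_nodes' must be a positive integer", call. = FALSE)
  chk_prob(p$p_delta, "p_delta")
  chk_prob(p$p_r, "p_r")
  if (!is.numeric(p$w0) || p$w0 <= 0) stop("'w0' must be > 0", call. = FALSE)
  if (!is.numeric(p$delta) || p$delta < 0)
    stop("'delta' must be >= 0", call. = FALSE)
  if (is.na(p$steps) || p$steps < 0)
    stop("'steps' must be >= 0", call. = FALSE)
  switch(p$mechanism,
    ND = chk_prob(p$p_nd, "p_nd"),
    LD = chk_prob(p$p_ld, "p_ld"),
    AGING = {
      f <- p$aging_factor
      if (is.null(f) || !is.numeric(f) || f <= 0 || f >= 1)
        stop("'aging_factor' must lie strictly in (0,1)", call. = FALSE)
      if (is.null(p$w_th) || !is.numeric(p$w_th) || p$w_th <= 0)
        stop("'w_th' must be > 0", call. = FALSE)
    })
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Tie-formation model parameters (%s mechanism)\n", x$mechanism))
  cat(sprintf("  N = %d, steps = %d, seed = %d\n", x$n_nodes, x$steps, x$seed))
  cat(sprintf("  p_delta = %g, p_r = %g, w0 = %g, delta = %g\n",
              x$p_delta, x$p_r, x$w0, x$delta))
  extra <- switch(x$mechanism,
    ND = sprintf("  p_nd = %g", x$p_nd),
    LD = sprintf("  p_ld = %g", x$p_ld),
    AGING = sprintf("  f = %g, w_th = %g", x$aging_factor, x$w_th))
  cat(extra, "\n")
  invisible(x)
}

mechanism_code <- function(mechanism) {
  c(ND = 0L, LD = 1L, AGING = 2L)[[mechanism]]
}
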