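#' Probability that a given tie is reinforced by one local-attachment event
#'
#' In an isolated clique of size n, a single local-attachment event traces a
#' uniformly random triangle; a fixed tie belongs to `n - 2` of the
#' `choose(n, 3)` triangles, so
#' `p = (n - 2) / choose(n, 3) = 6 / (n (n - 1))`.
#' The expected per-step weight gain of a tie is `p * n * delta`, because
#' every one of the n clique members initiates one event per step.
#'
#' @param n Clique size (>= 3; a triangle is the minimal closing structure).
#' @return The probability p.
#' @export
la_pick_probability <- function(n) {
  if (any(n < 3)) stop("clique size must be >= 3", call. = FALSE)
  6 / (n * (n - 1))
}

#' Equilibrium tie weight of a clique community under aging
#'
#' Balancing the expected per-step reinforcement `p n delta = 6 delta/(n-1)`
#' against the aging loss `(1 - f) <w>` gives
#' `<w> = 6 delta / ((1 - f)(n - 1))`.
#' The implied node strength `s = <w> (n - 1) = 6 delta / (1 - f)` is
#' independent of the community size — the flat strength-versus-degree
#' profile of the aging model.
#'
#' @param n Clique size (>= 3).
#' @param f Aging factor in (0, 1).
#' @param delta Reinforcement increment (default 1).
#' @return The equilibrium mean weight.
#' @export
clique_equilibrium_weight <- function(n, f, delta = 1) {
  if (any(n < 3)) stop("clique size must be >= 3", call. = FALSE)
  if (any(f <= 0) || any(f >= 1)) stop("f must lie in (0, 1)", call. = FALSE)
  6 * delta / ((1 - f) * (n - 1))
}

#' Deterministic clique weight map and its stability
#'
#' Iterates the mean-field update `w <- f (w + p n delta)` — reinforcement
#' followed by aging, matching the engine's within-step ordering — from
#' `w_init`. The map is linear with contraction factor f, hence globally
#' stable with fixed point `w* = f 6 delta / ((1 - f)(n - 1))`, which
#' approaches [clique_equilibrium_weight()] as f -> 1. The contraction
#' factor is reported as the numerical stability certificate.
#'
#' @inheritParams clique_equilibrium_weight
#' @param w_init Initial weight.
#' @param n_steps Number of iterations.
#' @return List with the `trajectory` (length `n_steps + 1`), `fixed_point`,
#'   and `contraction_factor` (= f).
#' @export
clique_weight_map <- function(n, f, delta = 1, w_init = 1, n_steps = 100) {
  p <- la_pick_probability(n)
  if (f <= 0 || f >= 1) stop("f must lie in (0, 1)", call. = FALSE)
  w <- numeric(n_steps + 1)
  w[1] <- w_init
  for (t in seq_len(n_steps)) w[t + 1] <- f * (w[t] + p * n * delta)
  list(trajectory = w,
       fixed_point = f * p * n * delta / (1 - f),
       contraction_factor = f)
}

#' Predicted link-weight distribution exponent
#'
#' For ND and LD, weights grow exponentially with tie age (rate `1/tau_r`)
#' while ties die at a constant rate (`1/tau_d`), giving
#' `P(w) ~ w^-(1 + tau_r/tau_d)`; the exponent approaches -1 when
#' reinforcement is much faster than removal. For the aging model the
#' small-weight branch (w < w0) comes from un-reinforced ties decaying
#' exponentially under a uniform age distribution, giving exponent -1
#' independent of parameters.
#'
#' @param mechanism `"ND"`, `"LD"`, or `"AGING"`.
#' @param tau_r Reinforcement time constant (ND/LD; > 0).
#' @param tau_d Removal time constant (ND/LD; > 0).
#' @return The predicted exponent (a negative number).
#' @export
weight_exponent_prediction <- function(mechanism = c("ND", "LD", "AGING"),
                                       tau_r = NULL, tau_d = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "AGING") return(-1)
  if (is.null(tau_r) || is.null(tau_d) || tau_r <= 0 || tau_d <= 0)
    stop("tau_r and tau_d must be positive for ND/LD", call. = FALSE)
  -(1 + tau_r / tau_d)
}
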