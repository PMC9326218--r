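#' Firing-rate activation function
#'
#' Maps a membrane potential to a firing rate through the positive part of a
#' hyperbolic tangent: `F = max(0, tanh(V - theta))`. Rates therefore lie in
#' `[0, 1)`: units below threshold are silent, and even saturated units never
#' reach 1.
#'
#' @param V membrane potential (any real number; vectorized).
#' @param theta firing threshold (dimensionless, `>= 0`).
#' @return firing rate(s) in `[0, 1)`.
#' @examples
#' activation(0.5, 0)        # tanh(0.5)
#' activation(-2, 0)         # clipped to 0
#' @export
activation <- function(V, theta) {
  stopifnot(is.numeric(V), is.numeric(theta), all(theta >= 0))
  pmax(0, tanh(V - theta))
}

#' Parameters of a leaky firing-rate unit
#'
#' @param tau membrane time constant, in integration time steps (`> 0`).
#' @param theta firing threshold (`>= 0`).
#' @param rho BCM plasticity threshold in `[0, 1)`; shared across a unit's
#'   plastic afferents unless a connection overrides it.
#' @return a list of class `unit_params`.
#' @export
unit_params <- function(tau = 10, theta = 0, rho = 0.3) {
  stopifnot(tau > 0, theta >= 0, rho >= 0, rho < 1)
  structure(list(tau = tau, theta = theta, rho = rho),
            class = "unit_params")
}

#' State of a leaky firing-rate unit
#'
#' `F` is kept consistent with `V` through [activation()].
#'
#' @param V membrane potential.
#' @param theta firing threshold used to derive `F`.
#' @return a list of class `unit_state` with elements `V` and `F`.
#' @export
unit_state <- function(V = 0, theta = 0) {
  stopifnot(is.finite(V))
  structure(list(V = V, F = activation(V, theta)), class = "unit_state")
}

#' One Euler step of the leaky-unit dynamics
#'
#' Integrates `tau * dV/dt = -V + I + syn_input` with a forward Euler step of
#' size `dt`, then recomputes the firing rate. At a constant total input the
#' potential relaxes exponentially towards `I + syn_input`.
#'
#' @param state a [unit_state()].
#' @param params a [unit_params()].
#' @param I external input to the unit.
#' @param syn_input summed weighted presynaptic rates, `sum(w * F_pre)`.
#' @param dt step size; must satisfy `0 < dt <= tau` for stability.
#' @return the updated `unit_state`.
#' @export
euler_step <- function(state, params, I = 0, syn_input = 0, dt = 1) {
  stopifnot(inherits(state, "unit_state"), inherits(params, "unit_params"))
  if (!all(is.finite(c(I, syn_input, dt)))) {
    stop("euler_step: inputs must be finite")
  }
  if (dt <= 0 || dt > params$tau) {
    stop("euler_step: need 0 < dt <= tau")
  }
  V <- state$V + dt / params$tau * (-state$V + I + syn_input)
  unit_state(V = V, theta = params$theta)
}

#' Clip a weight to its bounds
#'
#' @param w weight value (vectorized).
#' @param w_min,w_max lower and upper bound, `w_min <= w_max`.
#' @return the clipped weight.
#' @export
clip_weight <- function(w, w_min, w_max) {
  if (any(w_min > w_max)) stop("clip_weight: w_min must not exceed w_max")
  pmin(w_max, pmax(w_min, w))
}

#' A directed, possibly plastic connection
#'
#' @param pre,post unit identifiers.
#' @param weight initial signed weight.
#' @param plastic does the weight learn at all?
#' @param alpha learning rate per step (`>= 0`); 0 freezes the weight.
#' @param w_min,w_max clip bounds enforced after every update.
#' @param psi_modulated should the cortical plasticity gain `psi` multiply
#'   this connection's learning rate (true for sensory-to-PFC connections)?
#' @return a list of class `connection`.
#' @export
connection <- function(pre, post, weight, plastic = FALSE, alpha = 0,
                       w_min = -Inf, w_max = Inf, psi_modulated = FALSE) {
  stopifnot(alpha >= 0, w_min <= w_max,
            weight >= w_min, weight <= w_max)
  structure(list(pre = pre, post = post, weight = weight, plastic = plastic,
                 alpha = alpha, w_min = w_min, w_max = w_max,
                 psi_modulated = psi_modulated),
            class = "connection")
}

#' BCM weight update
#'
#' Applies the simplified Bienenstock-Cooper-Munro rule
#' `dw = alpha * g * (F_post - rho) * F_pre`, where the gain `g` equals `psi`
#' for psi-modulated (cortical) connections and 1 otherwise, then clips the
#' weight to the connection's bounds. The postsynaptic rate relative to the
#' sliding threshold `rho` decides between potentiation (`F_post > rho`) and
#' depression (`F_post < rho`); a silent presynaptic unit gates the update
#' off entirely. Non-plastic connections are returned unchanged.
#'
#' @param conn a [connection()].
#' @param F_pre,F_post pre- and postsynaptic firing rates in `[0, 1)`.
#' @param rho plasticity threshold.
#' @param psi cortical plasticity gain (`> 0`); only applied when
#'   `conn$psi_modulated` is `TRUE`.
#' @return the connection with its weight updated.
#' @export
bcm_update <- function(conn, F_pre, F_post, rho, psi = 1) {
  stopifnot(inherits(conn, "connection"),
            F_pre >= 0, F_pre <= 1, F_post >= 0, F_post <= 1, psi > 0)
  if (!conn$plastic || conn$alpha == 0) return(conn)
  gain <- if (conn$psi_modulated) psi else 1
  dw <- conn$alpha * gain * (F_post - rho) * F_pre
  conn$weight <- clip_weight(conn$weight + dw, conn$w_min, conn$w_max)
  conn
}
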