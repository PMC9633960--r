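#' Izhikevich neuron parameters for a model region
#'
#' All regions share the reset constants `c = -65` mV and `d = 8`. The
#' recovery constants `(a, b)` differ by region: the D1-expressing striatal
#' population uses `(0.01, 0.01)`, the D2-expressing population `(0.1, 0.5)`,
#' and every other region `(0.02, 0.6)`.
#'
#' @param region one of `"other"`, `"StrD1"`, `"StrD2"`.
#' @return list with fields `a`, `b`, `c`, `d`.
#' @export
izh_params <- function(region = c("other", "StrD1", "StrD2")) {
  region <- match.arg(region)
  ab <- switch(region,
    StrD1 = c(0.01, 0.01),
    StrD2 = c(0.1, 0.5),
    other = c(0.02, 0.6)
  )
  list(a = ab[1], b = ab[2], c = -65, d = 8, region = region)
}

#' Resting state of an Izhikevich neuron
#'
#' `v = -65` mV and `u = b * v`, the fixed point of the recovery equation.
#'
#' @param params neuron parameters from [izh_params()].
#' @param n number of neurons (vectorised state).
#' @return list with numeric vectors `v` and `u` of length `n`.
#' @export
izh_rest <- function(params, n = 1L) {
  list(v = rep(-65, n), u = rep(params$b * -65, n))
}

#' Advance one Izhikevich neuron by one forward-Euler step
#'
#' Integrates `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)` by one
#' step of size `dt`. If the advanced membrane potential reaches the 30 mV
#' spike cut-off, the after-spike reset `v <- c`, `u <- u + d` is applied and
#' `fired = TRUE` is returned.
#'
#' @param state list with scalar `v` (mV) and `u`.
#' @param params neuron parameters from [izh_params()].
#' @param input_current dimensionless synaptic drive `I`.
#' @param dt integration step in ms (default 0.5).
#' @return list with `state` (the post-step `v`, `u`), `fired` (logical) and
#'   `v_spike` (the pre-reset advanced voltage, used for winner-take-all).
#' @export
step_neuron <- function(state, params, input_current, dt = 0.5) {
  if (!is.finite(state$v) || !is.finite(state$u) || !is.finite(input_current)) {
    stop(
      "non-finite neuron state or input (v = ", state$v, ", u = ", state$u,
      ", I = ", input_current, "): numerical divergence"
    )
  }
  if (dt <= 0) stop("dt must be positive")
  st <- step_population(list(v = state$v, u = state$u), params, input_current, dt)
  list(
    state = list(v = st$v, u = st$u),
    fired = st$fired,
    v_spike = st$v_pre
  )
}

#' Advance a population of Izhikevich neurons by one forward-Euler step
#'
#' Vectorised version of [step_neuron()]: `v`, `u` and `input_current` are
#' aligned numeric vectors. Resets are applied synchronously at the end of the
#' step to every neuron whose advanced voltage reached 30 mV.
#'
#' @param state list with numeric vectors `v`, `u`.
#' @param params neuron parameters from [izh_params()] (shared by the
#'   population).
#' @param input_current numeric vector or scalar drive.
#' @param dt integration step in ms.
#' @return list with vectors `v`, `u`, logical `fired`, and `v_pre` (advanced
#'   voltage before reset).
#' @export
step_population <- function(state, params, input_current, dt = 0.5) {
  v <- state$v
  u <- state$u
  if (any(!is.finite(v)) || any(!is.finite(u)) || any(!is.finite(input_current))) {
    stop("non-finite population state or input: numerical divergence")
  }
  v_pre <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  u_pre <- u + dt * (params$a * (params$b * v - u))
  fired <- v_pre >= 30
  v_post <- ifelse(fired, params$c, v_pre)
  u_post <- ifelse(fired, u_pre + params$d, u_pre)
  list(v = v_post, u = u_post, fired = fired, v_pre = v_pre)
}

#' Synaptic input current from presynaptic spikes
#'
#' Implements `I = W * O` accumulated over presynaptic sources: with a weight
#' vector (one entry per presynaptic neuron) and a binary spike vector the
#' current delivered to the single target is `sum(W * O)`. With a weight
#' matrix (presynaptic rows, target columns) a current per target column is
#' returned.
#'
#' @param weights non-negative numeric vector or matrix of synaptic weights.
#' @param spikes binary (0/1 or logical) presynaptic output vector.
#' @return numeric scalar (vector weights) or vector of per-target currents.
#' @export
synaptic_input <- function(weights, spikes) {
  spikes <- as.numeric(spikes)
  if (!all(spikes %in% c(0, 1))) stop("spikes must be binary 0/1")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  if (is.matrix(weights)) {
    if (nrow(weights) != length(spikes)) {
      stop(
        "shape mismatch: ", nrow(weights), " presynaptic weights vs ",
        length(spikes), " spikes"
      )
    }
    return(as.numeric(crossprod(weights, spikes)))
  }
  if (length(weights) != length(spikes)) {
    stop(
      "shape mismatch: ", length(weights), " weights vs ",
      length(spikes), " spikes"
    )
  }
  sum(weights * spikes)
}

#' Winner-take-all competition among simultaneously firing neurons
#'
#' When several neurons cross the spike threshold in the same step, the one
#' with the largest membrane voltage suppresses the rest. Exact voltage ties
#' are broken toward the lowest neuron index so the pipeline is deterministic.
#'
#' @param ids integer ids of the candidate (fired) neurons.
#' @param voltages membrane voltages of the candidates, aligned with `ids`.
#' @return the single surviving neuron id, or `NA_integer_` when the
#'   candidate set is empty (the "no spike" sentinel).
#' @export
winner_take_all <- function(ids, voltages) {
  if (length(ids) == 0L) return(NA_integer_)
  if (length(ids) != length(voltages)) stop("ids and voltages must align")
  ids <- as.integer(ids)
  ids[order(-voltages, ids)][1L]
}
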