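#' STDP parameters
#'
#' Defaults are the constants fitted to biological pairing data:
#' `A_plus = 0.777`, `A_minus = -0.237`, `tau_plus = 16.8` ms and
#' `tau_minus = -33.7` ms (the depression time constant is negative as
#' printed, so the depression branch exponent `delta_t / tau_minus` decays
#' for increasingly positive lags).
#'
#' @param A_plus potentiation learning rate (dimensionless, positive).
#' @param A_minus depression learning rate (dimensionless, negative).
#' @param tau_plus potentiation time constant (ms, positive).
#' @param tau_minus depression time constant (ms, negative).
#' @return validated list of the four constants.
#' @export
stdp_params <- function(A_plus = 0.777, A_minus = -0.237,
                        tau_plus = 16.8, tau_minus = -33.7) {
  stopifnot(A_plus > 0, A_minus < 0, tau_plus > 0, tau_minus < 0)
  list(A_plus = A_plus, A_minus = A_minus,
       tau_plus = tau_plus, tau_minus = tau_minus)
}

#' STDP weight-change ratio for a spike-timing difference
#'
#' `delta_t` is the presynaptic (DLPFC) spike time minus the postsynaptic
#' (BG) spike time. Pre-before-post (`delta_t < 0`) yields potentiation
#' `A_plus * exp(delta_t / tau_plus) > 0`; post-before-or-with-pre
#' (`delta_t >= 0`) yields depression `A_minus * exp(delta_t / tau_minus) < 0`.
#' Vectorised over `delta_t`.
#'
#' @param delta_t spike-timing difference(s) in ms.
#' @param params STDP constants from [stdp_params()].
#' @return weight-change ratio(s) `delta_w`, strictly positive iff
#'   `delta_t < 0`.
#' @export
stdp_delta <- function(delta_t, params = stdp_params()) {
  ifelse(delta_t < 0,
    params$A_plus * exp(delta_t / params$tau_plus),
    params$A_minus * exp(delta_t / params$tau_minus)
  )
}

#' Apply a ratio-based multiplicative weight update
#'
#' The plastic entry `(i, j)` becomes `w * (1 + delta_w)`, then is clamped
#' from below at `floor` so that a long run of depression events can never
#' drive a weight to an absorbing zero (the multiplicative rule cannot regrow
#' an exactly-zero weight). All other entries are untouched.
#'
#' @param weights positive numeric weight matrix (state rows, intention
#'   columns).
#' @param i,j row (state) and column (intention) index of the entry to update.
#' @param delta_w weight-change ratio; must exceed -1 so positivity is
#'   preserved.
#' @param floor lower clamp for the updated entry.
#' @return the updated weight matrix.
#' @export
apply_multiplicative_update <- function(weights, i, j, delta_w,
                                        floor = 1e-3) {
  if (!is.matrix(weights)) stop("weights must be a matrix")
  if (i < 1 || i > nrow(weights) || j < 1 || j > ncol(weights)) {
    stop("index (", i, ", ", j, ") out of range for ",
         nrow(weights), "x", ncol(weights), " weights")
  }
  if (!is.finite(delta_w) || delta_w <= -1) {
    stop("delta_w must be finite and > -1 (got ", delta_w,
         "): update would annihilate or flip the weight sign")
  }
  weights[i, j] <- max(weights[i, j] * (1 + delta_w), floor)
  weights
}

#' Write a plastic weight matrix to CSV
#'
#' One row per state category, one column per intention; the header row
#' carries 1-based intention labels and the first column 1-based state
#' labels, matching the user-facing "intention 1..N" numbering.
#'
#' @param weights weight matrix.
#' @param path output file path.
#' @export
write_weights_csv <- function(weights, path) {
  df <- as.data.frame(weights)
  names(df) <- paste0("intention_", seq_len(ncol(weights)))
  df <- cbind(state = paste0("state_", seq_len(nrow(weights))), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plastic weight matrix written by [write_weights_csv()]
#'
#' @param path CSV file path.
#' @return numeric weight matrix.
#' @export
read_weights_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
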