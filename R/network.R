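REGION_NAMES <- c(
  "DLPFC", "StrD1", "StrD2", "BG_output", "Thalamus", "PMC",
  "SNc_VTA", "OFC_1", "OFC_2", "MOFC", "LOFC"
)

#' Build the intention-prediction network topology
#'
#' Constructs the full region set (DLPFC, striatal D1/D2 populations, basal
#' ganglia output, thalamus, primary motor cortex, SNc/VTA, the orbitofrontal
#' relays OFC_1/OFC_2 and their medial/lateral divisions). Every region is an
#' `N x N` neuron grid except PMC, which is `1 x N`. Exactly one projection
#' is plastic - DLPFC to BG - initialised uniformly at `w0` so the very first
#' prediction is decided by the deterministic lowest-index tie-break; all
#' other projections carry a fixed suprathreshold relay weight.
#'
#' @param n_intentions number of state categories / intentions `N` (>= 1).
#' @param config an [intent_config()]; its `n_intentions` is overridden by
#'   the explicit argument.
#' @return object of class `intent_network` with fields `n`, `regions`
#'   (data frame of shapes), `edges` (data frame with `from`, `to`,
#'   `weight`, `plastic`, `inhibitory`), `W` (the plastic matrix), `config`
#'   and a weight `version` counter.
#' @export
build_network <- function(n_intentions, config = intent_config()) {
  if (length(n_intentions) != 1L || !is.finite(n_intentions) ||
      n_intentions < 1) {
    stop("n_intentions must be a single integer >= 1")
  }
  n <- as.integer(n_intentions)
  config$n_intentions <- n
  regions <- data.frame(
    name = REGION_NAMES,
    rows = ifelse(REGION_NAMES == "PMC", 1L, n),
    cols = n,
    stringsAsFactors = FALSE
  )
  edge <- function(from, to, plastic = FALSE, inhibitory = FALSE) {
    data.frame(
      from = from, to = to,
      weight = if (plastic) NA_real_ else config$fixed_weight,
      plastic = plastic, inhibitory = inhibitory,
      stringsAsFactors = FALSE
    )
  }
  edges <- rbind(
    edge("DLPFC", "BG", plastic = TRUE),
    edge("StrD1", "BG_output"),
    edge("StrD2", "BG_output"),
    edge("BG_output", "Thalamus"),
    edge("Thalamus", "PMC"),
    edge("Thalamus", "OFC_1"),
    edge("PMC", "SNc_VTA"),
    edge("SNc_VTA", "OFC_2"),
    edge("OFC_1", "MOFC"),
    edge("OFC_2", "LOFC"),
    edge("MOFC", "StrD1"),
    edge("MOFC", "DLPFC"),
    edge("MOFC", "LOFC", inhibitory = TRUE),
    edge("LOFC", "StrD2"),
    edge("LOFC", "DLPFC")
  )
  structure(
    list(
      n = n,
      regions = regions,
      edges = edges,
      W = matrix(config$w0, n, n),
      config = config,
      version = 0L
    ),
    class = "intent_network"
  )
}

#' @export
print.intent_network <- function(x, ...) {
  cat("<intent_network> N =", x$n, "intentions\n")
  cat("  regions:", nrow(x$regions), "| plastic edge: DLPFC -> BG",
      sprintf("(%dx%d, version %d)\n", x$n, x$n, x$version))
  invisible(x)
}

#' Encode a discrete state as a DLPFC drive pattern
#'
#' Activating state `s` means delivering a constant drive current to every
#' neuron of DLPFC row `s` for the stimulus window; all other DLPFC neurons
#' receive zero drive.
#'
#' @param network an `intent_network`.
#' @param state_index state category in `1..N`.
#' @return `N x N` drive matrix with `drive_current` in row `state_index`.
#' @export
encode_state <- function(network, state_index) {
  n <- network$n
  if (length(state_index) != 1L || state_index < 1 || state_index > n) {
    stop("state_index must be in 1..", n)
  }
  drive <- matrix(0, n, n)
  drive[state_index, ] <- network$config$drive_current
  drive
}

#' Run one feed-forward trial and select an intention
#'
#' Simulates the stimulus-locked spike volley for one trial window: the
#' stimulated DLPFC category row is integrated under constant drive; once it
#' spikes, its (latched) output feeds the basal-ganglia grid through the
#' plastic weights; the first BG threshold crossing is resolved by
#' winner-take-all (largest membrane voltage, lowest index on exact ties) and
#' the winning column is the selected intention. The volley is then relayed
#' through the thalamus and PMC neurons at the fixed weight, and all spike
#' times are recorded for plasticity.
#'
#' Because the forward-Euler voltage step is monotone in the input current
#' and all BG neurons start from the same rest state, this procedure always
#' selects `argmax` over the stimulated row of the plastic weight matrix with
#' lowest-index tie-break.
#'
#' @param network an `intent_network`.
#' @param state_index state category in `1..N` (or a drive matrix from
#'   [encode_state()]).
#' @return list of class `trial_record`: `state`, `intention`, spike times
#'   `t_dlpfc`, `t_bg`, `t_thalamus`, `t_pmc` (ms), and the weight `version`
#'   the trial was run against.
#' @export
forward_pass <- function(network, state_index) {
  cfg <- network$config
  n <- network$n
  if (is.matrix(state_index)) {
    rows <- which(rowSums(state_index != 0) > 0)
    if (length(rows) != 1L) stop("drive pattern must activate exactly one row")
    state_index <- rows
  }
  if (state_index < 1 || state_index > n) stop("state_index must be in 1..", n)
  s <- as.integer(state_index)
  p <- cfg$neuron_params$other
  dt <- cfg$dt
  n_steps <- ceiling(cfg$window_ms / dt)

  dlpfc <- izh_rest(p, n)          # the stimulated category row
  bg <- izh_rest(p, n * n)         # full BG grid, column-major (row, col)
  bg_drive <- rep(0, n * n)
  dlpfc_latched <- FALSE
  t_dlpfc <- NA_real_
  winner <- NA_integer_
  t_bg <- NA_real_

  for (step in seq_len(n_steps)) {
    dl <- step_population(dlpfc, p, cfg$drive_current, dt)
    dlpfc <- dl[c("v", "u")]
    if (!dlpfc_latched && any(dl$fired)) {
      dlpfc_latched <- TRUE
      t_dlpfc <- step * dt
      # latched presynaptic output: row s drives BG entry (s, j) with W[s, j]
      bg_drive <- as.numeric(vapply(
        seq_len(n),
        function(j) synaptic_input(network$W[s, j], 1),
        numeric(1)
      ))
      idx <- s + (seq_len(n) - 1L) * n
      full <- rep(0, n * n)
      full[idx] <- bg_drive
      bg_drive <- full
    }
    bgs <- step_population(bg, p, bg_drive, dt)
    bg <- bgs[c("v", "u")]
    if (any(bgs$fired)) {
      ids <- which(bgs$fired)
      winner <- winner_take_all(ids, bgs$v_pre[ids])
      t_bg <- step * dt
      break
    }
  }
  if (is.na(winner)) {
    stop("no BG spike within the trial window: drive/weight misconfiguration")
  }
  intention <- ((winner - 1L) %/% n) + 1L

  # relay volley: BG winner -> thalamus -> PMC at the fixed weight
  relay <- function(t_pre) {
    st <- izh_rest(p)
    for (step in seq_len(n_steps)) {
      t_now <- t_pre + step * dt
      out <- step_population(st, p, synaptic_input(cfg$fixed_weight, 1), dt)
      st <- out[c("v", "u")]
      if (out$fired) return(t_now)
    }
    stop("relay neuron failed to fire within the trial window")
  }
  t_thalamus <- relay(t_bg)
  t_pmc <- relay(t_thalamus)

  structure(
    list(
      state = s,
      intention = intention,
      t_dlpfc = t_dlpfc,
      t_bg = t_bg,
      t_thalamus = t_thalamus,
      t_pmc = t_pmc,
      version = network$version
    ),
    class = "trial_record"
  )
}

#' Route a reward signal into plasticity events
#'
#' Positive feedback (predicted intention matches the user's) travels the
#' medial orbitofrontal pathway: one potentiation event on the active synapse
#' `(s, a)` (DLPFC fires before StrD1, negative lag), while the lateral
#' pathway - released for every other state because MOFC only inhibits the
#' active entry - issues depression events on `(s', a)` for all `s' != s`
#' (StrD2 fires before DLPFC, positive lag). This column-wise depression is
#' what steers future states away from already-claimed intentions. Negative
#' feedback silences SNc/VTA and only the lateral pathway acts: a single
#' depression event on `(s, a)`.
#'
#' @param network an `intent_network`.
#' @param valence `"positive"` or `"negative"`.
#' @param trial a `trial_record` from [forward_pass()].
#' @return data frame of plasticity events with columns `i` (state row),
#'   `j` (intention column), `delta_t` (nominal lag, ms) and `pathway`.
#' @export
route_reward <- function(network, valence = c("positive", "negative"), trial) {
  valence <- match.arg(valence)
  if (!inherits(trial, "trial_record") || is.na(trial$t_bg)) {
    stop("route_reward requires a completed trial record with spike timings")
  }
  s <- trial$state
  a <- trial$intention
  cfg <- network$config
  if (valence == "positive") {
    others <- setdiff(seq_len(network$n), s)
    rbind(
      data.frame(i = s, j = a, delta_t = cfg$lag_ltp, pathway = "MOFC"),
      if (length(others)) {
        data.frame(i = others, j = a, delta_t = cfg$lag_ltd, pathway = "LOFC")
      }
    )
  } else {
    data.frame(i = s, j = a, delta_t = cfg$lag_ltd, pathway = "LOFC")
  }
}

#' Export a topology summary as JSON
#'
#' @param network an `intent_network`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
topology_json <- function(network, path = NULL) {
  summary <- list(
    n_intentions = network$n,
    regions = network$regions,
    edges = network$edges
  )
  js <- jsonlite::toJSON(summary, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
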