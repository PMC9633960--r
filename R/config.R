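#' Run configuration for the intention-prediction network
#'
#' Collects every tunable of the simulator in one place. Defaults are the
#' model's published constants where such constants exist (neuron reset and
#' recovery parameters, STDP constants) and the package's documented design
#' choices elsewhere (integration step, drive amplitude, trial window,
#' nominal plasticity lags, initial and fixed weights, weight floor).
#'
#' @param n_intentions number of state categories / intentions `N`.
#' @param dt forward-Euler step in ms.
#' @param window_ms trial window: simulated time per prediction step.
#' @param drive_current constant input delivered to the stimulated DLPFC row.
#' @param fixed_weight constant weight on every non-plastic projection
#'   (suprathreshold single-spike relay).
#' @param w0 uniform initial value of the plastic DLPFC-to-BG weights.
#' @param weight_floor_frac weight floor as a fraction of `w0`.
#' @param lag_ltp nominal spike-timing difference (ms, negative) assigned to
#'   potentiation events routed via the medial orbitofrontal pathway.
#' @param lag_ltd nominal spike-timing difference (ms, positive) assigned to
#'   depression events routed via the lateral orbitofrontal pathway.
#' @param stdp STDP constants from [stdp_params()].
#' @param presentation default state presentation policy, `"sequential"`
#'   (state-by-state to criterion) or `"random"` (seedable shuffled state
#'   order, each state still trained to criterion).
#' @param seed optional integer seed for randomised presentation orders.
#' @return list of class `intent_config`.
#' @export
intent_config <- function(n_intentions = 12L,
                          dt = 0.5,
                          window_ms = 100,
                          drive_current = 20,
                          fixed_weight = 50,
                          w0 = 10,
                          weight_floor_frac = 1e-3,
                          lag_ltp = -10,
                          lag_ltd = 10,
                          stdp = stdp_params(),
                          presentation = c("sequential", "random"),
                          seed = NULL) {
  presentation <- match.arg(presentation)
  stopifnot(
    n_intentions >= 1, dt > 0, window_ms > 0, drive_current > 0,
    fixed_weight > 0, w0 > 0, weight_floor_frac > 0, weight_floor_frac < 1,
    lag_ltp < 0, lag_ltd >= 0
  )
  structure(
    list(
      n_intentions = as.integer(n_intentions),
      dt = dt,
      window_ms = window_ms,
      drive_current = drive_current,
      fixed_weight = fixed_weight,
      w0 = w0,
      weight_floor_frac = weight_floor_frac,
      lag_ltp = lag_ltp,
      lag_ltd = lag_ltd,
      stdp = stdp,
      presentation = presentation,
      seed = seed,
      neuron_params = list(
        StrD1 = izh_params("StrD1"),
        StrD2 = izh_params("StrD2"),
        other = izh_params("other")
      )
    ),
    class = "intent_config"
  )
}

#' Load a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [intent_config()]; STDP constants may be set
#' with top-level keys `A_plus`, `A_minus`, `tau_plus`, `tau_minus`. Keys not
#' present fall back to the built-in defaults, and `overrides` (e.g. parsed
#' CLI flags) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return an `intent_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("configuration file must be a YAML mapping")
  }
  vals <- modifyList(vals, overrides)
  stdp_keys <- c("A_plus", "A_minus", "tau_plus", "tau_minus")
  stdp_args <- vals[intersect(names(vals), stdp_keys)]
  vals <- vals[setdiff(names(vals), stdp_keys)]
  if (length(stdp_args)) vals$stdp <- do.call(stdp_params, stdp_args)
  known <- setdiff(names(formals(intent_config)), "...")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(intent_config, vals)
}

# Flatten a config to plain named values for logging / echoing into run logs.
config_as_record <- function(config) {
  c(
    config[c(
      "n_intentions", "dt", "window_ms", "drive_current", "fixed_weight",
      "w0", "weight_floor_frac", "lag_ltp", "lag_ltd", "presentation"
    )],
    config$stdp,
    list(seed = if (is.null(config$seed)) NA else config$seed)
  )
}

#' Append one event to a JSON-lines run log
#'
#' @param path log file path (created on first write).
#' @param event named list; a timestamp is added.
#' @export
log_jsonl <- function(path, event) {
  event$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  line <- jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA, null = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
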