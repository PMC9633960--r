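#' Validate a state-to-intention rule set
#'
#' A rule set is a bijection from the `N` state categories onto the `N`
#' intentions, given as a permutation vector: `rule[s]` is the intention
#' (1-based) the user intends for state `s`.
#'
#' @param rule integer vector; a permutation of `1..length(rule)`.
#' @return the validated integer rule vector.
#' @export
rule_set <- function(rule) {
  rule <- as.integer(rule)
  n <- length(rule)
  if (n < 1 || !identical(sort(rule), seq_len(n))) {
    stop("rule must be a permutation of 1..N (each intention used once)")
  }
  rule
}

#' Predict the intention for a state without learning
#'
#' Pure read-out: runs one feed-forward trial ([forward_pass()]) and returns
#' the selected intention. Weights are not modified.
#'
#' @param network an `intent_network`.
#' @param state_index state category in `1..N`.
#' @return intention index in `1..N`.
#' @export
predict_intention <- function(network, state_index) {
  forward_pass(network, state_index)$intention
}

#' Apply right/wrong feedback to the network
#'
#' Converts the reward-routing events of [route_reward()] into STDP ratios at
#' the configured nominal lags and applies them multiplicatively to the
#' plastic matrix. Positive feedback strictly increases `w(s, a)` and
#' strictly decreases `w(s', a)` for every other state `s'`; negative
#' feedback strictly decreases `w(s, a)` only.
#'
#' @param network an `intent_network`.
#' @param trial the `trial_record` of the immediately preceding prediction.
#' @param valence `"positive"` or `"negative"`.
#' @return the updated network (weight `version` incremented).
#' @export
apply_feedback <- function(network, trial, valence) {
  if (!inherits(trial, "trial_record")) stop("trial must be a trial_record")
  if (trial$version != network$version) {
    stop("stale trial record: weights have changed since this prediction ",
         "(record version ", trial$version, ", network version ",
         network$version, ")")
  }
  events <- route_reward(network, valence, trial)
  cfg <- network$config
  floor <- cfg$weight_floor_frac * cfg$w0
  for (k in seq_len(nrow(events))) {
    dw <- stdp_delta(events$delta_t[k], cfg$stdp)
    network$W <- apply_multiplicative_update(
      network$W, events$i[k], events$j[k], dw, floor = floor
    )
  }
  network$version <- network$version + 1L
  network
}

# Train the given states (in the given order) to criterion on an existing
# network. Shared engine behind train_rule_set() and
# relearn_after_rule_change(). Returns network + transcript + counts.
train_states <- function(network, rule, state_order, max_trials) {
  n <- network$n
  transcript <- vector("list", max_trials)
  count <- 0L
  per_state <- integer(n)
  for (s in state_order) {
    repeat {
      if (count >= max_trials) {
        stop("training did not terminate within ", max_trials,
             " trials: broken update semantics")
      }
      trial <- forward_pass(network, s)
      correct <- trial$intention == rule[s]
      valence <- if (correct) "positive" else "negative"
      count <- count + 1L
      per_state[s] <- per_state[s] + 1L
      transcript[[count]] <- data.frame(
        trial = count, state = s, intention = trial$intention,
        feedback = valence, stringsAsFactors = FALSE
      )
      network <- apply_feedback(network, trial, valence)
      if (correct) break
    }
  }
  list(
    network = network,
    transcript = do.call(rbind, transcript[seq_len(count)]),
    interactions = count,
    per_state = per_state
  )
}

resolve_state_order <- function(n, presentation, seed) {
  if (presentation == "random") {
    if (!is.null(seed)) set.seed(seed)
    sample.int(n)
  } else {
    seq_len(n)
  }
}

#' Train the network on a rule set through right/wrong feedback
#'
#' Runs the interaction protocol: present a state, let the network predict,
#' give positive feedback when the prediction matches `rule[state]` and
#' negative feedback otherwise, repeat. States are presented to criterion one
#' after another (default ascending order; `presentation = "random"` shuffles
#' the state order under `seed`). Training is complete when every state's
#' most recent presentation was predicted correctly; one interaction is one
#' (prediction, feedback) pair.
#'
#' @param rule a permutation vector (see [rule_set()]), or an
#'   `intent_network` plus `rule` via `network`.
#' @param network optional pre-built `intent_network`; by default a fresh
#'   uniform network of matching size is built.
#' @param config an [intent_config()] used when `network` is `NULL`.
#' @param presentation `"sequential"` or `"random"` state order (defaults to
#'   the configuration's policy).
#' @param seed seed for the random presentation order.
#' @return object of class `training_result`: `interactions` (total feedback
#'   events), `per_state` counts, `W` (final weights), `network`,
#'   `transcript` (one row per trial) and `rule`.
#' @export
train_rule_set <- function(rule, network = NULL, config = intent_config(),
                           presentation = NULL, seed = NULL) {
  rule <- rule_set(rule)
  n <- length(rule)
  if (is.null(network)) network <- build_network(n, config)
  if (network$n != n) stop("network size ", network$n, " != rule size ", n)
  presentation <- presentation %||% network$config$presentation
  seed <- seed %||% network$config$seed
  order <- resolve_state_order(n, presentation, seed)
  fit <- train_states(network, rule, order, max_trials = n * (n + 1L))
  final_pred <- apply(fit$network$W, 1, which.max)
  stopifnot(identical(as.integer(final_pred), rule))
  structure(
    list(
      interactions = fit$interactions,
      per_state = fit$per_state,
      W = fit$network$W,
      network = fit$network,
      transcript = fit$transcript,
      rule = rule
    ),
    class = "training_result"
  )
}

#' @export
print.training_result <- function(x, ...) {
  cat("<training_result> N =", length(x$rule),
      "| interactions =", x$interactions, "\n")
  cat("  rule:", paste(x$rule, collapse = " "), "\n")
  invisible(x)
}

#' Continue training after the user changes some rules
#'
#' Starting from a network already trained to criterion, retrains on the new
#' rule set with the same interaction protocol. Because weights update as
#' ratios of their current value, the strengthened old association decays
#' quickly under repeated negative feedback, while rows whose rule did not
#' change keep their learned maximum and are predicted correctly at their
#' first post-change presentation (cost exactly one interaction).
#'
#' @param trained a `training_result` (or an `intent_network` trained to
#'   criterion on the old rule).
#' @param new_rule the changed permutation vector.
#' @param presentation,seed as in [train_rule_set()].
#' @return a `training_result` with two extra fields: `changed_states` and
#'   `abandon_counts` (per changed state, the number of wrong predictions of
#'   its old intention before it was abandoned).
#' @export
relearn_after_rule_change <- function(trained, new_rule,
                                      presentation = NULL, seed = NULL) {
  network <- if (inherits(trained, "training_result")) trained$network else trained
  if (!inherits(network, "intent_network")) {
    stop("trained must be a training_result or intent_network")
  }
  new_rule <- rule_set(new_rule)
  n <- network$n
  if (length(new_rule) != n) stop("rule size mismatch")
  old_pred <- apply(network$W, 1, which.max)
  presentation <- presentation %||% network$config$presentation
  seed <- seed %||% network$config$seed
  order <- resolve_state_order(n, presentation, seed)
  # worst case per state: a few abandonment trials on the entrenched old
  # intention plus up to N candidate probes
  fit <- train_states(network, new_rule, order,
                      max_trials = n * (n + 1L) + 8L * n)
  changed <- which(old_pred != new_rule)
  abandon <- vapply(changed, function(s) {
    rows <- fit$transcript[fit$transcript$state == s, , drop = FALSE]
    sum(rows$intention == old_pred[s] & rows$feedback == "negative")
  }, integer(1))
  final_pred <- apply(fit$network$W, 1, which.max)
  stopifnot(identical(as.integer(final_pred), new_rule))
  structure(
    list(
      interactions = fit$interactions,
      per_state = fit$per_state,
      W = fit$network$W,
      network = fit$network,
      transcript = fit$transcript,
      rule = new_rule,
      changed_states = changed,
      abandon_counts = setNames(abandon, changed)
    ),
    class = "training_result"
  )
}

#' Write an interaction transcript as JSON Lines
#'
#' One JSON object per trial with fields `trial`, `state`, `intention`,
#' `feedback`.
#'
#' @param result a `training_result`.
#' @param path output file path.
#' @export
write_transcript_jsonl <- function(result, path) {
  tr <- result$transcript
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(tr))) {
    writeLines(jsonlite::toJSON(as.list(tr[k, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
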