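#' Reproduce the rule-space comparison experiment
#'
#' Enumerates the rule space for each `N` in `n_min..n_max` (exhaustively,
#' or by seeded sampling for large `N`), runs the reconstructed Q-learning
#' baseline, and writes the five-row comparison table as CSV together with a
#' pass/fail check against the closed forms (min `N`, max `N(N+1)/2`, mode
#' `(N + N(N+1)/2)/2`, baseline `N(N+1)/2`). Optionally writes an
#' extended-range JSON report of the closed-form curves.
#'
#' @param n_min,n_max intention-number range for the table.
#' @param mode `"exhaustive"` (requires `n_max <= 10`) or `"sampled"`.
#' @param n_samples rules sampled per `N` in sampled mode.
#' @param seed integer seed for sampled mode.
#' @param out optional CSV output path.
#' @param extended_out optional JSON output path for the closed-form curves
#'   over `extended_range`.
#' @param extended_range intention numbers covered by the extended report.
#' @param log optional JSON-lines run-log path.
#' @param config an [intent_config()]; echoed into the run log.
#' @return list with `table` (data frame), `checks` (per-N logical
#'   closed-form agreement) and `extended` (data frame or NULL).
#' @export
run_table1 <- function(n_min = 1, n_max = 9,
                       mode = c("exhaustive", "sampled"),
                       n_samples = 1e5, seed = 1L,
                       out = NULL, extended_out = NULL,
                       extended_range = 1:50,
                       log = NULL, config = intent_config()) {
  mode <- match.arg(mode)
  n_range <- seq.int(n_min, n_max)
  if (!is.null(log)) {
    log_jsonl(log, c(list(event = "run_table1", mode = mode, seed = seed),
                     config_as_record(config)))
  }
  if (mode == "exhaustive") {
    tab <- comparison_table(n_range)
  } else {
    cols <- lapply(n_range, function(n) {
      dist <- distribution_over_rules(n, "sampled", n_samples = n_samples,
                                      seed = seed + n)
      set.seed(seed + n)
      q <- q_learning_count(sample.int(n))
      c(factorial(n), q, dist$mode, dist$min, dist$max)
    })
    tab <- as.data.frame(cols)
    names(tab) <- as.character(n_range)
    tab <- cbind(
      statistic = c("Number of rules", "Q-learning method",
                    "The proposed model (Mode)", "The proposed model (Min)",
                    "The proposed model (Max)"),
      tab
    )
  }
  closed <- function(n) {
    c(factorial(n), n * (n + 1) / 2, (n + n * (n + 1) / 2) / 2,
      n, n * (n + 1) / 2)
  }
  checks <- vapply(seq_along(n_range), function(k) {
    got <- as.numeric(tab[, k + 1])
    want <- closed(n_range[k])
    if (mode == "sampled") {
      # sampling cannot visit every extreme rule; check the mode estimate
      # and the bound direction only
      abs(got[3] - want[3]) <= 1 && got[4] >= want[4] && got[5] <= want[5]
    } else {
      isTRUE(all.equal(got, want))
    }
  }, logical(1))
  names(checks) <- as.character(n_range)
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE, quote = FALSE)
  extended <- NULL
  if (!is.null(extended_out)) {
    extended <- data.frame(
      n = extended_range,
      q_learning = extended_range * (extended_range + 1) / 2,
      model_mode = (extended_range +
                      extended_range * (extended_range + 1) / 2) / 2,
      model_min = extended_range,
      model_max = extended_range * (extended_range + 1) / 2,
      improvement = (extended_range^2 - extended_range) / 4
    )
    jsonlite::write_json(extended, extended_out, dataframe = "rows",
                         digits = NA)
  }
  if (!is.null(log)) {
    log_jsonl(log, list(event = "run_table1_done",
                        all_checks_pass = all(checks)))
  }
  list(table = tab, checks = checks, extended = extended)
}

#' Reproduce the rule-change (relearning) experiment
#'
#' Trains a fresh network on `old_rule`, then retrains on `new_rule`,
#' reporting per-state relearning costs, confirming that every unchanged
#' state costs exactly one interaction, and optionally exporting the weight
#' matrices before and after the change as CSV heat-map data.
#'
#' @param old_rule,new_rule permutation vectors of equal length.
#' @param config an [intent_config()].
#' @param out_dir optional directory for `weights_before.csv`,
#'   `weights_after.csv` and the two interaction transcripts.
#' @param log optional JSON-lines run-log path.
#' @return list with `train` and `relearn` training results, a `per_state`
#'   report data frame and `unchanged_cost_one` (logical).
#' @export
run_rule_change <- function(old_rule, new_rule, config = intent_config(),
                            out_dir = NULL, log = NULL) {
  old_rule <- rule_set(old_rule)
  new_rule <- rule_set(new_rule)
  if (length(old_rule) != length(new_rule)) {
    stop("old and new rules must have the same number of intentions")
  }
  if (!is.null(log)) {
    log_jsonl(log, c(list(event = "run_rule_change",
                          old_rule = old_rule, new_rule = new_rule),
                     config_as_record(config)))
  }
  config$n_intentions <- length(old_rule)
  train <- train_rule_set(old_rule, config = config)
  relearn <- relearn_after_rule_change(train, new_rule)
  n <- length(old_rule)
  changed <- old_rule != new_rule
  per_state <- data.frame(
    state = seq_len(n),
    old_intention = old_rule,
    new_intention = new_rule,
    changed = changed,
    relearn_interactions = relearn$per_state,
    abandoned_old_after = ifelse(
      changed,
      as.integer(relearn$abandon_counts[as.character(seq_len(n))]),
      NA_integer_
    )
  )
  unchanged_cost_one <- all(relearn$per_state[!changed] == 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_weights_csv(train$W, file.path(out_dir, "weights_before.csv"))
    write_weights_csv(relearn$W, file.path(out_dir, "weights_after.csv"))
    write_transcript_jsonl(train, file.path(out_dir, "train_transcript.jsonl"))
    write_transcript_jsonl(relearn,
                           file.path(out_dir, "relearn_transcript.jsonl"))
    write.csv(per_state, file.path(out_dir, "per_state.csv"),
              row.names = FALSE, quote = FALSE)
  }
  if (!is.null(log)) {
    log_jsonl(log, list(event = "run_rule_change_done",
                        train_interactions = train$interactions,
                        relearn_interactions = relearn$interactions,
                        unchanged_cost_one = unchanged_cost_one))
  }
  list(train = train, relearn = relearn, per_state = per_state,
       unchanged_cost_one = unchanged_cost_one)
}

#' Run the synthetic gesture-learning demonstration
#'
#' Trains the online gesture classifier batch-wise on noisy synthetic
#' samples of the 12 gesture prototypes and reports the test accuracy after
#' each batch.
#'
#' @param noise per-feature flip probability.
#' @param batches number of training batches (one sample of each class per
#'   batch).
#' @param seed integer seed.
#' @param out optional CSV path for the accuracy curve.
#' @param log optional JSON-lines run-log path.
#' @return the [gesture_learning_curve()] result.
#' @export
run_gesture_demo <- function(noise = 0.05, batches = 6, seed = 1L,
                             out = NULL, log = NULL) {
  if (!is.null(log)) {
    log_jsonl(log, list(event = "run_gesture_demo", noise = noise,
                        batches = batches, seed = seed))
  }
  res <- gesture_learning_curve(n_batches = batches, flip_prob = noise,
                                seed = seed)
  if (!is.null(out)) {
    write.csv(
      data.frame(batch = seq_along(res$accuracy), accuracy = res$accuracy),
      out, row.names = FALSE, quote = FALSE
    )
  }
  if (!is.null(log)) {
    log_jsonl(log, list(event = "run_gesture_demo_done",
                        final_accuracy = res$accuracy[length(res$accuracy)],
                        n_neurons = res$n_neurons))
  }
  res
}
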