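test_that("feedback arithmetic follows the pairing rule at the nominal lags", {
  cfg <- intent_config(n_intentions = 2)
  ltp <- 1 + stdp_delta(cfg$lag_ltp, cfg$stdp)   # pre-before-post, potentiation
  ltd <- 1 + stdp_delta(cfg$lag_ltd, cfg$stdp)   # post-before-pre, depression

  # wrong feedback: only the active synapse is depressed
  net <- build_network(3, cfg)
  trial <- forward_pass(net, 2)
  net2 <- apply_feedback(net, trial, "negative")
  expect_equal(net2$W[2, 1], 10 * ltd)
  expect_equal(net2$W[2, 1], 10 * (1 - 0.237 * exp(10 / -33.7)))
  W_rest <- net2$W; W_rest[2, 1] <- 10
  expect_true(all(W_rest == 10))

  # right feedback: active synapse potentiated, its column depressed elsewhere
  net <- build_network(2, cfg)
  trial <- forward_pass(net, 1)
  net2 <- apply_feedback(net, trial, "positive")
  expect_equal(net2$W[1, 1], 10 * ltp)
  expect_equal(net2$W[1, 1], 10 * (1 + 0.777 * exp(-10 / 16.8)))
  expect_equal(net2$W[2, 1], 10 * ltd)
  expect_true(all(net2$W[, 2] == 10))

  # single-intention network: the only weight grows
  net1 <- build_network(1)
  t1 <- forward_pass(net1, 1)
  expect_equal(apply_feedback(net1, t1, "positive")$W[1, 1], 10 * ltp)
})

test_that("stale trial records are rejected", {
  net <- build_network(3)
  trial <- forward_pass(net, 1)
  net2 <- apply_feedback(net, trial, "negative")
  expect_error(apply_feedback(net2, trial, "negative"), "stale")
})

test_that("prediction is pure and matches the weight argmax", {
  net <- build_network(3)
  expect_identical(predict_intention(net, 2), 1L)     # uniform + tie-break
  res <- train_rule_set(c(1, 2, 3))
  expect_identical(predict_intention(res$network, 3), 3L)
  expect_identical(predict_intention(build_network(1), 1), 1L)
})

test_that("training counts match known rules and respect the bounds", {
  expect_identical(train_rule_set(1L)$interactions, 1L)          # N = 1
  expect_identical(train_rule_set(c(1, 2, 3))$interactions, 3L)  # identity
  expect_identical(train_rule_set(c(3, 2, 1))$interactions, 6L)  # full reversal
  res <- train_rule_set(c(2, 3, 1, 4))
  expect_identical(as.integer(apply(res$W, 1, which.max)), c(2L, 3L, 1L, 4L))
  n <- 4
  expect_gte(res$interactions, n)
  expect_lte(res$interactions, n * (n + 1) / 2)
  expect_identical(nrow(res$transcript), res$interactions)
  # feedback valence in the transcript is consistent with the rule
  with(res$transcript, expect_identical(
    feedback == "positive", c(2, 3, 1, 4)[state] == intention
  ))
})

test_that("spiking interaction counts equal the elimination oracle for all rules, N <= 4", {
  for (n in 1:4) {
    for (rule in all_perms(n)) {
      expect_identical(train_rule_set(rule)$interactions,
                       ref_elimination_count(rule))
    }
  }
})

test_that("learned rules are absorbing: no forgetting without a rule change", {
  set.seed(3)
  for (k in 1:10) {
    n <- sample(3:6, 1)
    rule <- sample(n)
    res <- train_rule_set(rule)
    net <- res$network
    for (s in sample(n, 2 * n, replace = TRUE)) {
      trial <- forward_pass(net, s)
      expect_identical(trial$intention, rule[s])
      net <- apply_feedback(net, trial, "positive")  # extra rewards don't break it
    }
  }
})

test_that("interaction-count distribution is invariant to the state presentation order", {
  # multiset of counts over all rules is the same for any state order
  counts_for_order <- function(order, n) {
    sort(vapply(all_perms(n), function(rule) {
      ref_elimination_count(rule, order)
    }, integer(1)))
  }
  base <- counts_for_order(1:4, 4)
  set.seed(9)
  for (k in 1:5) {
    expect_identical(counts_for_order(sample(4), 4), base)
  }
  # and the spiking loop agrees under a shuffled presentation
  res <- train_rule_set(c(2, 4, 1, 3), presentation = "random", seed = 21)
  set.seed(21)
  order <- sample.int(4)
  expect_identical(res$interactions,
                   ref_elimination_count(c(2, 4, 1, 3), order))
})

test_that("rule changes are relearned without disturbing unchanged rules", {
  # swap two rules in a trained N=4 network: unchanged states cost exactly 1
  res <- train_rule_set(c(1, 2, 3, 4))
  new_rule <- c(2L, 1L, 3L, 4L)
  rel <- relearn_after_rule_change(res, new_rule)
  expect_identical(as.integer(apply(rel$W, 1, which.max)), new_rule)
  expect_true(all(rel$per_state[3:4] == 1L))
  expect_setequal(rel$changed_states, c(1, 2))
  expect_true(all(rel$abandon_counts >= 1))

  # unchanged rule set: every prediction already correct, cost N
  rel2 <- relearn_after_rule_change(res, c(1, 2, 3, 4))
  expect_identical(rel2$interactions, 4L)

  # full reversal: all states relearn, final mapping correct
  rel3 <- relearn_after_rule_change(res, c(4, 3, 2, 1))
  expect_identical(as.integer(apply(rel3$W, 1, which.max)), c(4L, 3L, 2L, 1L))
  expect_length(rel3$changed_states, 4L)
})

test_that("unchanged-rule preservation holds over random rule-change draws", {
  set.seed(17)
  for (n in c(4, 6, 8)) {
    for (k in 1:34) {
      old <- sample(n)
      res <- train_rule_set(old)
      # random change: permute the intentions of a random subset of states
      subset <- sample(n, sample(2:n, 1))
      new <- old
      if (length(subset) > 1) new[subset] <- old[sample(subset)]
      rel <- relearn_after_rule_change(res, new)
      unchanged <- which(old == new)
      expect_true(all(rel$per_state[unchanged] == 1L))
      expect_identical(as.integer(apply(rel$W, 1, which.max)), as.integer(new))
    }
  }
})

test_that("transcripts export as JSON lines", {
  res <- train_rule_set(c(2, 1, 3))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcript_jsonl(res, path)
  lines <- readLines(path)
  expect_length(lines, res$interactions)
  rec <- jsonlite::fromJSON(lines[1])
  expect_setequal(names(rec), c("trial", "state", "intention", "feedback"))
})

test_that("malformed rules are rejected", {
  expect_error(rule_set(c(1, 1, 2)), "permutation")
  expect_error(rule_set(c(2, 3)), "permutation")
  expect_error(rule_set(integer(0)), "permutation")
  expect_error(train_rule_set(c(1, 2), network = build_network(3)), "size")
})
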