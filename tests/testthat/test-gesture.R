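test_that("feature space and prototypes have the published structure", {
  feats <- gesture_feature_names()
  expect_length(feats, 20L)
  expect_length(grep("^left_hand_", feats), 10L)
  expect_length(grep("overlaps|above", feats), 8L)
  proto <- gesture_prototypes()
  expect_identical(dim(proto), c(12L, 20L))
  expect_true(all(proto %in% 0:1))
  expect_identical(rownames(proto), LETTERS[1:12])
  # gesture J engages both above-shoulder positions
  expect_identical(
    unname(proto["J", c("left_hand_above_left_shoulder",
                        "right_hand_above_right_shoulder")]),
    c(1L, 1L)
  )
  # every class is separable from every other under the default threshold
  C <- stats::cor(t(proto))
  diag(C) <- 0
  expect_lt(max(C), 0.5)
})

test_that("joint-stream encoding computes each feature from the stated geometry", {
  # both hands approach the torso beyond the cutoff: toward-body features fire
  stream <- synthetic_joint_stream("A")
  pat <- encode_joint_stream(stream)
  expect_identical(unname(pat[c("left_hand_toward_body",
                                "right_hand_toward_body")]), c(1L, 1L))

  # static stream, hands at the hips: all 20 features silent
  static <- synthetic_joint_stream("A")
  static[static$joint %in% c("left_hand", "right_hand"), c("x", "y", "z")] <-
    matrix(rep(c(0, -30, 10), each = 20), ncol = 3)
  expect_identical(sum(encode_joint_stream(static)), 0L)

  # right hand moved up by twice the cutoff: up fires among movement features
  sw <- 30
  up <- data.frame(
    frame = rep(1:2, 4),
    joint = rep(c("left_hand", "right_hand", "left_shoulder",
                  "right_shoulder"), each = 2),
    x = c(-15, -15, 15, 15, -15, -15, 15, 15),
    y = c(-30, -30, -30, -30 + 2 * 0.15 * sw, 0, 0, 0, 0),
    z = c(10, 10, 10, 10, 0, 0, 0, 0)
  )
  pat_up <- encode_joint_stream(up)
  moves <- grep("overlaps|above", gesture_feature_names(),
                invert = TRUE, value = TRUE)
  expect_identical(unname(pat_up["right_hand_up"]), 1L)
  expect_identical(sum(pat_up[moves]), 1L)

  # every synthetic stream realises its gesture's prototype exactly
  proto <- gesture_prototypes()
  for (g in LETTERS[1:12]) {
    expect_identical(
      unname(encode_joint_stream(synthetic_joint_stream(g))),
      unname(proto[g, ]),
      info = paste("gesture", g)
    )
  }

  expect_error(encode_joint_stream(stream[stream$joint != "left_hand", ]),
               "missing required joint")
})

test_that("encoding is deterministic for identical streams", {
  s1 <- synthetic_joint_stream("F")
  expect_identical(encode_joint_stream(s1), encode_joint_stream(s1))
})

test_that("online classification recruits, matches and rejects as specified", {
  st <- gesture_classifier()
  proto <- gesture_prototypes()
  # first observation recruits class 1
  r1 <- classify_online(st, proto["A", ], label = "A")
  expect_true(r1$is_new)
  expect_identical(r1$class, 1L)
  st <- r1$state
  # identical pattern: same class, correlation 1
  r2 <- classify_online(st, proto["A", ], label = "A")
  expect_false(r2$is_new)
  expect_identical(r2$class, 1L)
  expect_equal(r2$correlation, 1)
  st <- r2$state
  # pattern sharing no active feature: recruited as new
  r3 <- classify_online(st, proto["J", ], label = "J")
  expect_true(r3$is_new)
  expect_lt(r3$correlation, 0.5)
  # all-zero input is rejected as no gesture
  expect_error(classify_online(st, rep(0, 20)), "no gesture")
  expect_error(classify_online(st, rep(2, 20)), "binary")
})

test_that("a 13th orthogonal pattern always recruits a new neuron", {
  proto <- gesture_prototypes()
  set.seed(13)
  for (k in 1:20) {
    st <- gesture_classifier()
    for (g in sample(LETTERS[1:12])) {
      st <- classify_online(st, proto[g, ], label = g)$state
    }
    unused <- which(colSums(proto) == 0)
    novel <- rep(0L, 20)
    novel[sample(unused, 3)] <- 1L
    res <- classify_online(st, novel, label = "new")
    expect_true(res$is_new)
    expect_identical(res$class, 13L)
  }
})

test_that("synthetic gesture sets are seed-deterministic with the stated noise", {
  a <- generate_synthetic_gestures(12, 30, 0.05, seed = 4)
  b <- generate_synthetic_gestures(12, 30, 0.05, seed = 4)
  expect_identical(a, b)
  expect_identical(dim(a$patterns), c(360L, 20L))
  expect_identical(length(a$labels), 360L)
  # zero noise reproduces the prototypes exactly
  clean <- generate_synthetic_gestures(12, 2, 0, seed = 1)
  proto <- gesture_prototypes()
  for (i in seq_along(clean$labels)) {
    expect_identical(unname(clean$patterns[i, ]),
                     unname(proto[clean$labels[i], ]))
  }
  expect_error(generate_synthetic_gestures(13), "12")
  expect_error(generate_synthetic_gestures(12, 1, 0.5), "flip_prob")
})

test_that("online learning reaches high accuracy and improves over batches", {
  for (s in 1:5) {
    curve <- gesture_learning_curve(n_batches = 6, flip_prob = 0.05, seed = s)
    expect_length(curve$accuracy, 6L)
    # >= 90% on the 360-sample noisy test set after six batches
    expect_gte(curve$accuracy[6], 0.9)
    expect_gte(curve$accuracy[6], curve$accuracy[1])
    # accuracy is an empirical proportion over 360 samples: require
    # non-decrease up to a single test sample per step
    expect_true(all(diff(curve$accuracy) >= -1 / 360 - 1e-12))
    expect_gte(curve$n_neurons, 12L)
  }
})

test_that("gesture sets round-trip through CSV", {
  samples <- generate_synthetic_gestures(3, 2, 0.1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gestures_csv(samples, path)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), 6L)
  expect_identical(names(df), c(gesture_feature_names(), "label"))
  expect_identical(unname(as.matrix(df[, 1:20])), unname(samples$patterns))
})

test_that("trajectory states one-hot encode onto six action neurons", {
  states <- trajectory_states()
  expect_identical(nrow(states), 6L)
  expect_identical(states$action[states$state == "line_centered"],
                   "move_forward")
  expect_identical(states$action[states$state == "no_line"], "move_backward")
  for (lab in states$state) {
    enc <- encode_trajectory_state(lab)
    expect_identical(sum(enc), 1L)
    expect_identical(unname(which(enc == 1L)),
                     states$index[states$state == lab])
  }
  expect_identical(unname(encode_trajectory_state("line_centered")[1]), 1L)
  expect_identical(unname(encode_trajectory_state("no_line")[2]), 1L)
  expect_error(encode_trajectory_state("diagonal"), "unknown trajectory state")
})

test_that("trajectory sequences are seedable and feed the network as states", {
  seq1 <- generate_trajectory_sequence(40, "clockwise", seed = 6)
  expect_identical(seq1, generate_trajectory_sequence(40, "clockwise", seed = 6))
  expect_true(all(seq1 %in% trajectory_states()$state))
  expect_false("line_turns_left" %in% seq1)   # clockwise course turns right
  # a trained 6-state network executes the intended action for each view
  states <- trajectory_states()
  res <- train_rule_set(states$index, config = intent_config(n_intentions = 6))
  for (lab in unique(seq1)) {
    s <- which(encode_trajectory_state(lab) == 1L)
    expect_identical(predict_intention(res$network, s),
                     states$index[states$state == lab])
  }
})
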