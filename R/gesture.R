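#' Names of the 20 gesture feature neurons
#'
#' Twelve movement features (per hand: up, down, left, right, toward the
#' body, away from the body) and eight position features (per hand: overlaps
#' the left shoulder, overlaps the right shoulder, above the left shoulder,
#' above the right shoulder).
#'
#' @return character vector of length 20.
#' @export
gesture_feature_names <- function() {
  moves <- c("up", "down", "move_left", "move_right", "toward_body",
             "away_from_body")
  pos <- c("overlaps_left_shoulder", "overlaps_right_shoulder",
           "above_left_shoulder", "above_right_shoulder")
  c(
    paste0("left_hand_", moves), paste0("right_hand_", moves),
    paste0("left_hand_", pos), paste0("right_hand_", pos)
  )
}

#' Binary feature prototypes of the 12 predefined gestures
#'
#' Gesture A: both hands toward the body. B: one hand away from the body.
#' C: one hand moves left. D: one hand moves right. E: one hand up. F: one
#' hand down. G: both hands move down. H: one hand above the left shoulder.
#' I: one hand above the right shoulder. J: both hands above both
#' shoulders. K: left hand overlapping the left shoulder. L: right hand
#' overlapping the right shoulder. Single-hand gestures use the right hand
#' (except K, defined on the left).
#'
#' Prototypes include the kinematic side-effects of executing each gesture
#' with a shoulder-pivoted arm: a push away extends forward while the hand
#' drops and drifts inward; a cross-body swipe arcs in and ends brushing
#' the opposite shoulder; an outward sweep starts from a slight backswing
#' and ends at the near shoulder; a plain raise arcs forward; a chopping
#' drop falls outward while returning to the torso plane; raising one hand
#' above a shoulder passes through upward plus lateral movement (the
#' two-handed overhead gesture is a held pose); and touching a shoulder
#' lifts the hand and pulls it in. The resulting patterns are chosen so
#' that no two classes share more than one feature, equal-sized classes
#' share none, and no prototype is a subset of another: any pattern
#' corrupted by a single feature flip still correlates most strongly with
#' its own class, and between-class correlations stay at or below 0.45,
#' under the default novelty threshold.
#'
#' @return 12 x 20 binary matrix, rows named `A`..`L`, columns
#'   [gesture_feature_names()].
#' @export
gesture_prototypes <- function() {
  feats <- gesture_feature_names()
  proto <- matrix(0L, 12, length(feats),
                  dimnames = list(LETTERS[1:12], feats))
  on <- function(g, f) proto[g, f] <<- 1L
  on("A", c("left_hand_toward_body", "right_hand_toward_body"))
  on("B", c("right_hand_away_from_body", "right_hand_down",
            "right_hand_move_left"))
  on("C", c("right_hand_move_left", "right_hand_toward_body",
            "right_hand_overlaps_left_shoulder"))
  on("D", c("right_hand_move_right", "right_hand_away_from_body",
            "right_hand_overlaps_right_shoulder"))
  on("E", c("right_hand_up", "right_hand_away_from_body"))
  on("F", c("right_hand_down", "right_hand_move_right",
            "right_hand_toward_body"))
  on("G", c("left_hand_down", "right_hand_down"))
  on("H", c("right_hand_above_left_shoulder", "right_hand_move_left",
            "right_hand_up"))
  on("I", c("right_hand_above_right_shoulder", "right_hand_move_right",
            "right_hand_up"))
  on("J", c("left_hand_above_left_shoulder",
            "right_hand_above_right_shoulder"))
  on("K", c("left_hand_overlaps_left_shoulder", "left_hand_up",
            "left_hand_toward_body"))
  on("L", c("right_hand_overlaps_right_shoulder", "right_hand_up",
            "right_hand_toward_body"))
  proto
}

#' Encode a 3-D joint stream as a 20-feature gesture pattern
#'
#' The stream is a data frame with columns `frame`, `joint`, `x`, `y`, `z`
#' carrying at least the joints `left_hand`, `right_hand`, `left_shoulder`,
#' `right_shoulder` (units are arbitrary but consistent; `x` grows to the
#' subject's right, `y` upward, `z` away from the torso toward the camera).
#' A movement feature fires when the hand's net displacement along its axis
#' exceeds the displacement cutoff (default 15% of the shoulder width):
#' up/down along `y`, left/right along `x`, toward/away from the body along
#' the depth axis `z` (decreasing `z` approaches the torso plane). Position
#' features use the last frame: overlap fires when the hand lies within the
#' overlap radius (default 10% of the shoulder width) of a shoulder; above
#' fires when the hand is directly above a shoulder (laterally within half
#' the shoulder width) and exceeds its height by the displacement cutoff.
#'
#' @param stream joint stream data frame (>= 2 frames, finite coordinates).
#' @param displacement_frac displacement cutoff as a fraction of shoulder
#'   width.
#' @param overlap_frac overlap radius as a fraction of shoulder width.
#' @return named binary vector of length 20.
#' @export
encode_joint_stream <- function(stream, displacement_frac = 0.15,
                                overlap_frac = 0.10) {
  required <- c("left_hand", "right_hand", "left_shoulder", "right_shoulder")
  missing <- setdiff(required, unique(stream$joint))
  if (length(missing)) {
    stop("joint stream is missing required joint(s): ",
         paste(missing, collapse = ", "))
  }
  coords <- function(joint) {
    m <- stream[stream$joint == joint, c("frame", "x", "y", "z")]
    m <- as.matrix(m[order(m$frame), c("x", "y", "z")])
    if (nrow(m) < 2) stop("joint stream needs at least 2 frames per joint")
    if (any(!is.finite(m))) stop("joint stream contains non-finite coordinates")
    m
  }
  lh <- coords("left_hand"); rh <- coords("right_hand")
  ls <- coords("left_shoulder"); rs <- coords("right_shoulder")
  shoulder_width <- mean(sqrt(rowSums((ls - rs)^2)))
  cut <- displacement_frac * shoulder_width
  radius <- overlap_frac * shoulder_width
  lateral <- 0.5 * shoulder_width
  last <- nrow(lh)

  hand_features <- function(hand) {
    disp <- hand[last, ] - hand[1, ]
    c(
      up = disp[2] > cut,
      down = disp[2] < -cut,
      move_left = disp[1] < -cut,
      move_right = disp[1] > cut,
      toward_body = disp[3] < -cut,
      away_from_body = disp[3] > cut
    )
  }
  position_features <- function(hand) {
    h <- hand[last, ]
    above <- function(sh) {
      abs(h[1] - sh[1]) <= lateral && (h[2] - sh[2]) > cut
    }
    c(
      overlaps_left_shoulder = sqrt(sum((h - ls[last, ])^2)) < radius,
      overlaps_right_shoulder = sqrt(sum((h - rs[last, ])^2)) < radius,
      above_left_shoulder = above(ls[last, ]),
      above_right_shoulder = above(rs[last, ])
    )
  }
  pattern <- as.integer(c(
    hand_features(lh), hand_features(rh),
    position_features(lh), position_features(rh)
  ))
  setNames(pattern, gesture_feature_names())
}

#' Synthetic joint stream realising one of the 12 gesture prototypes
#'
#' Builds a short skeletal recording (shoulders 30 units apart, hands
#' starting at the hips) whose encoding under [encode_joint_stream()] equals
#' the gesture's prototype pattern: movement gestures displace the hand by
#' twice the displacement cutoff along the gesture's axis; pose gestures end
#' with the hand at the required position relative to the shoulders.
#'
#' @param gesture one of `"A"`..`"L"`.
#' @param n_frames number of frames (>= 2).
#' @param jitter_sd standard deviation of Gaussian coordinate jitter
#'   (0 = noiseless; keep well below the cutoffs to preserve the pattern).
#' @return joint stream data frame (`frame`, `joint`, `x`, `y`, `z`).
#' @export
synthetic_joint_stream <- function(gesture, n_frames = 10, jitter_sd = 0) {
  stopifnot(gesture %in% LETTERS[1:12], n_frames >= 2)
  sw <- 30                      # shoulder width
  step <- 2 * 0.15 * sw         # twice the displacement cutoff
  ls0 <- c(-sw / 2, 0, 0); rs0 <- c(sw / 2, 0, 0)
  lh0 <- c(-sw / 2, -sw, 10); rh0 <- c(sw / 2, -sw, 10)
  lh1 <- lh0; rh1 <- rh0
  move <- function(p, d) p + d
  if (gesture == "A") {                     # both hands pulled in (depth)
    lh1 <- move(lh0, c(0, 0, -step)); rh1 <- move(rh0, c(0, 0, -step))
  } else if (gesture == "B") {              # push: extends, drops, drifts in
    rh1 <- move(rh0, c(-step, -step, step))
  } else if (gesture == "C") {              # cross-body swipe ends at left shoulder
    rh1 <- ls0 + c(0.5, 0.5, 0.5); rh0 <- rh1 + c(step, 0, step)
  } else if (gesture == "D") {              # outward sweep from a backswing
    rh1 <- rs0 + c(0.5, 0.5, 0.5); rh0 <- rh1 + c(-step, 0, -step)
  } else if (gesture == "E") {              # forward raise arcs away
    rh1 <- move(rh0, c(0, step, step))
  } else if (gesture == "F") {              # chopping drop falls outward, tucks in
    rh0 <- c(sw / 3, -sw / 3, 10); rh1 <- move(rh0, c(step, -step, -step))
  } else if (gesture == "G") {
    lh1 <- move(lh0, c(0, -step, 0)); rh1 <- move(rh0, c(0, -step, 0))
  } else if (gesture == "H") {              # cross-body raise above left shoulder
    rh1 <- ls0 + c(0, 0.3 * sw, 2); rh0 <- rh1 + c(step, -step, 0)
  } else if (gesture == "I") {              # outward raise above own shoulder
    rh1 <- rs0 + c(0, 0.3 * sw, 2); rh0 <- rh1 + c(-step, -step, 0)
  } else if (gesture == "J") {              # held pose, both hands overhead
    lh1 <- ls0 + c(0, 0.3 * sw, 2); rh1 <- rs0 + c(0, 0.3 * sw, 2)
    lh0 <- lh1 + c(0, -0.1 * sw, 0); rh0 <- rh1 + c(0, -0.1 * sw, 0)
  } else if (gesture == "K") {              # hand lifts and tucks to shoulder
    lh1 <- ls0 + c(0.5, 0.5, 0.5); lh0 <- lh1 + c(0, -step, step)
  } else if (gesture == "L") {
    rh1 <- rs0 + c(0.5, 0.5, 0.5); rh0 <- rh1 + c(0, -step, step)
  }
  interp <- function(p0, p1) {
    t <- seq(0, 1, length.out = n_frames)
    outer(t, p1 - p0) + matrix(p0, n_frames, 3, byrow = TRUE)
  }
  paths <- list(
    left_hand = interp(lh0, lh1), right_hand = interp(rh0, rh1),
    left_shoulder = interp(ls0, ls0), right_shoulder = interp(rs0, rs0)
  )
  out <- do.call(rbind, lapply(names(paths), function(j) {
    m <- paths[[j]]
    if (jitter_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, jitter_sd),
                                       nrow(m), 3)
    data.frame(frame = seq_len(n_frames), joint = j,
               x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Create an empty online gesture classifier
#'
#' One target neuron is recruited per novel gesture; each neuron keeps a
#' vector of synaptic weights over the 20 feature neurons, initialised from
#' the recruiting pattern and sharpened by multiplicative STDP updates on
#' every later match (potentiation for co-active features, depression for
#' silent ones). An incoming pattern is assigned to the target neuron whose
#' weight vector correlates with it most strongly (Pearson), provided that
#' correlation reaches the novelty threshold `theta`; otherwise the gesture
#' is declared new.
#'
#' @param theta novelty threshold in (0, 1). The default 0.5 sits above the
#'   largest between-prototype correlation of the 12 gesture patterns
#'   (0.42) and below the correlation a pattern missing one feature still
#'   has with its own class (0.69), so every prototype recruits its own
#'   neuron while moderately corrupted samples still match.
#' @param stdp STDP constants from [stdp_params()].
#' @param lag_ltp,lag_ltd nominal pairing lags (ms) for match updates. The
#'   defaults are asymmetric by design: potentiation is gentle (long lag,
#'   about +7% per match), so one corrupted sample of another class that
#'   happens to be absorbed cannot drag a template away from its class,
#'   while depression is strong (short lag, about -18% per match), so a
#'   spurious feature frozen into a template at recruitment decays within a
#'   few clean matches. Templates therefore converge to their class
#'   prototype, and a class blocked by an unlucky recruitment recovers.
#' @param w_silent initial weight of features silent in the recruiting
#'   pattern.
#' @return object of class `gesture_classifier`.
#' @export
gesture_classifier <- function(theta = 0.5, stdp = stdp_params(),
                               lag_ltp = -40, lag_ltd = 10,
                               w_silent = 0.05) {
  stopifnot(theta > 0, theta < 1, w_silent > 0, w_silent < 1)
  structure(
    list(
      W = matrix(numeric(0), nrow = 0, ncol = 20,
                 dimnames = list(NULL, gesture_feature_names())),
      labels = character(0),
      label_counts = list(),
      theta = theta,
      stdp = stdp,
      lag_ltp = lag_ltp,
      lag_ltd = lag_ltd,
      w_silent = w_silent
    ),
    class = "gesture_classifier"
  )
}

#' Classify one gesture pattern online
#'
#' Computes the Pearson correlation between the binary pattern and every
#' learned target neuron's weight vector. If the best correlation reaches
#' the novelty threshold the pattern is assigned to that neuron and the
#' neuron's synapses are updated by STDP (potentiation on active features,
#' depression on inactive ones); otherwise a new target neuron is recruited
#' and initialised from the pattern.
#'
#' @param state a `gesture_classifier`.
#' @param pattern binary vector of length 20 with at least one active
#'   feature.
#' @param label optional provenance label stored on recruitment (used only
#'   for evaluating accuracy; learning itself is unsupervised).
#' @return list with `class` (target neuron index), `label` (the matched
#'   neuron's stored label), `is_new`, `correlation` (best correlation, NA
#'   for the first pattern) and `state` (the updated classifier).
#' @export
classify_online <- function(state, pattern, label = NA_character_) {
  pattern <- as.numeric(pattern)
  if (length(pattern) != 20 || !all(pattern %in% c(0, 1))) {
    stop("pattern must be a binary vector of length 20")
  }
  if (sum(pattern) == 0) stop("all-zero pattern rejected: no gesture detected")
  best_r <- NA_real_
  best_k <- NA_integer_
  if (nrow(state$W) > 0) {
    r <- apply(state$W, 1, function(w) stats::cor(w, pattern))
    best_k <- which.max(r)
    best_r <- r[best_k]
  }
  if (!is.na(best_r) && best_r >= state$theta) {
    dw_plus <- stdp_delta(state$lag_ltp, state$stdp)
    dw_minus <- stdp_delta(state$lag_ltd, state$stdp)
    w <- state$W[best_k, ]
    w <- w * ifelse(pattern == 1, 1 + dw_plus, 1 + dw_minus)
    w <- pmax(w, 1e-4)
    w <- w / max(w)                       # keep weights bounded; Pearson
    state$W[best_k, ] <- w                # correlation is scale-invariant
    state <- tally_label(state, best_k, label)
    list(class = best_k, label = neuron_labels(state)[best_k],
         is_new = FALSE, correlation = best_r, state = state)
  } else {
    w0 <- ifelse(pattern == 1, 1, state$w_silent)
    state$W <- rbind(state$W, w0)
    rownames(state$W) <- NULL
    state$labels <- c(state$labels, label)
    state$label_counts <- c(state$label_counts, list(integer(0)))
    k <- nrow(state$W)
    state <- tally_label(state, k, label)
    list(class = k, label = label, is_new = TRUE,
         correlation = best_r, state = state)
  }
}

tally_label <- function(state, k, label) {
  if (is.na(label)) return(state)
  counts <- state$label_counts[[k]]
  counts[label] <- (if (label %in% names(counts)) counts[[label]] else 0L) + 1L
  state$label_counts[[k]] <- counts
  state
}

#' Provenance labels of the recruited target neurons
#'
#' Learning is unsupervised; labels are bookkeeping only. A neuron's label
#' is the majority label over all labelled patterns it has absorbed (the
#' recruiting pattern included), which makes the evaluation robust to a
#' corrupted sample having recruited or been absorbed by the "wrong"
#' neuron.
#'
#' @param state a `gesture_classifier`.
#' @return character vector, one label per target neuron (`NA` where no
#'   labelled pattern was seen).
#' @export
neuron_labels <- function(state) {
  vapply(state$label_counts, function(counts) {
    if (length(counts) == 0) NA_character_ else names(which.max(counts))
  }, character(1))
}

#' Generate a labelled synthetic gesture pattern set
#'
#' Each sample is the prototype of its class with independent feature flips
#' at probability `flip_prob`, emulating imperfect skeletal feature
#' extraction. Deterministic for a fixed seed.
#'
#' @param n_classes number of gesture classes (<= 12).
#' @param samples_per_class samples drawn per class.
#' @param flip_prob per-feature flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list with `patterns` (binary matrix, one row per sample) and
#'   `labels` (gesture letters).
#' @export
generate_synthetic_gestures <- function(n_classes = 12, samples_per_class = 1,
                                        flip_prob = 0.05, seed = 1L) {
  stopifnot(n_classes >= 1, samples_per_class >= 1)
  if (n_classes > 12) stop("n_classes > 12: only 12 gesture prototypes defined")
  if (flip_prob < 0 || flip_prob >= 0.5) stop("flip_prob must be in [0, 0.5)")
  proto <- gesture_prototypes()[seq_len(n_classes), , drop = FALSE]
  set.seed(seed)
  labels <- rep(rownames(proto), each = samples_per_class)
  patterns <- proto[labels, , drop = FALSE]
  if (flip_prob > 0) {
    flips <- matrix(runif(length(patterns)) < flip_prob,
                    nrow(patterns), ncol(patterns))
    patterns <- abs(patterns - flips * 1L)
  }
  rownames(patterns) <- NULL
  storage.mode(patterns) <- "integer"
  list(patterns = patterns, labels = labels)
}

#' Train the online classifier batch-wise and track test accuracy
#'
#' Follows the batch protocol: a batch presents one sample of each class;
#' after every batch the classifier is evaluated (without learning) on the
#' test set. A test sample is predicted by the label of the most-correlated
#' target neuron (threshold ignored at test time) and counts as correct when
#' that label matches its own.
#'
#' @param n_batches number of training batches.
#' @param n_classes gesture classes used.
#' @param test_samples_per_class test samples drawn per class.
#' @param flip_prob feature flip noise shared by train and test sets.
#' @param seed integer seed (distinct sub-seeds derive the test set and each
#'   batch).
#' @param theta novelty threshold of the classifier.
#' @return list with `accuracy` (per-batch test accuracy), `state` (final
#'   classifier) and `n_neurons` recruited.
#' @export
gesture_learning_curve <- function(n_batches = 6, n_classes = 12,
                                   test_samples_per_class = 30,
                                   flip_prob = 0.05, seed = 1L,
                                   theta = 0.5) {
  test <- generate_synthetic_gestures(
    n_classes, test_samples_per_class, flip_prob, seed = seed * 1000L + 999L
  )
  state <- gesture_classifier(theta = theta)
  acc <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    batch <- generate_synthetic_gestures(
      n_classes, 1, flip_prob, seed = seed * 1000L + b
    )
    for (k in seq_len(nrow(batch$patterns))) {
      pat <- batch$patterns[k, ]
      if (sum(pat) == 0) next  # noise silenced every feature: no gesture
      res <- classify_online(state, pat, label = batch$labels[k])
      state <- res$state
    }
    acc[b] <- gesture_accuracy(state, test$patterns, test$labels)
  }
  list(accuracy = acc, state = state, n_neurons = nrow(state$W))
}

#' Evaluate classifier accuracy on a labelled pattern set
#'
#' @param state a trained `gesture_classifier`.
#' @param patterns binary pattern matrix (one row per sample).
#' @param labels true labels aligned with `patterns`.
#' @return fraction of samples whose best-matching neuron carries the true
#'   label (all-zero patterns count as errors).
#' @export
gesture_accuracy <- function(state, patterns, labels) {
  if (nrow(state$W) == 0) return(0)
  nl <- neuron_labels(state)
  pred <- apply(patterns, 1, function(p) {
    if (sum(p) == 0) return(NA_character_)
    r <- apply(state$W, 1, function(w) stats::cor(w, as.numeric(p)))
    nl[which.max(r)]
  })
  mean(!is.na(pred) & pred == labels)
}

#' Write a labelled gesture pattern set to CSV
#'
#' One row per sample: the 20 feature columns followed by a `label` column.
#'
#' @param samples list from [generate_synthetic_gestures()].
#' @param path output file path.
#' @export
write_gestures_csv <- function(samples, path) {
  df <- as.data.frame(samples$patterns)
  names(df) <- gesture_feature_names()
  df$label <- samples$labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

TRAJECTORY_STATES <- c(
  "line_centered", "no_line", "line_left", "line_right",
  "line_turns_left", "line_turns_right"
)

TRAJECTORY_ACTIONS <- c(
  line_centered = "move_forward", no_line = "move_backward",
  line_left = "move_left", line_right = "move_right",
  line_turns_left = "turn_left", line_turns_right = "turn_right"
)

#' The six abstract trajectory states and their intended actions
#'
#' The track-following front-end reduces each camera frame to one of six
#' views of the black line; each view has one intended action (line centred:
#' move forward; no line: move backward; line left/right of the visual
#' field: move left/right; line turning: turn).
#'
#' @return data frame with `state`, `index` and `action`.
#' @export
trajectory_states <- function() {
  data.frame(
    state = TRAJECTORY_STATES,
    index = seq_along(TRAJECTORY_STATES),
    action = unname(TRAJECTORY_ACTIONS[TRAJECTORY_STATES]),
    stringsAsFactors = FALSE
  )
}

#' One-hot encode an abstract trajectory state
#'
#' @param label one of the six trajectory state labels (see
#'   [trajectory_states()]).
#' @return named binary vector of length 6 with exactly one active neuron;
#'   its index is directly usable as a state index for [build_network()]
#'   networks with `n_intentions = 6`.
#' @export
encode_trajectory_state <- function(label) {
  idx <- match(label, TRAJECTORY_STATES)
  if (length(label) != 1L || is.na(idx)) {
    stop("unknown trajectory state '", label, "'; expected one of: ",
         paste(TRAJECTORY_STATES, collapse = ", "))
  }
  setNames(as.integer(seq_along(TRAJECTORY_STATES) == idx), TRAJECTORY_STATES)
}

#' Generate a synthetic trajectory state sequence
#'
#' Emulates laps of a closed course: long centred stretches interrupted by
#' turns (direction set by `direction`), with occasional drift to the left
#' or right and rare line loss.
#'
#' @param n_steps sequence length.
#' @param direction `"clockwise"` (right turns) or `"counterclockwise"`.
#' @param seed integer seed.
#' @return character vector of trajectory state labels.
#' @export
generate_trajectory_sequence <- function(n_steps = 60,
                                         direction = c("clockwise",
                                                       "counterclockwise"),
                                         seed = 1L) {
  direction <- match.arg(direction)
  turn <- if (direction == "clockwise") "line_turns_right" else "line_turns_left"
  set.seed(seed)
  sample(
    c("line_centered", "line_left", "line_right", turn, "no_line"),
    n_steps, replace = TRUE,
    prob = c(0.6, 0.12, 0.12, 0.12, 0.04)
  )
}
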