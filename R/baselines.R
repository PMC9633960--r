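#' Training count of the tabular Q-learning baseline for one rule
#'
#' Reconstructed baseline: per-state independent tabular Q with zero
#' initialisation, greedy action selection with lowest-index tie-break,
#' rewards +1/-1, learning rate 1, no exploration noise. The agent probes
#' intentions in ascending index order for every state, so the total count
#' is `N(N+1)/2` for every permutation rule - the baseline has no mechanism
#' to exclude intentions already claimed by other states.
#'
#' @param rule permutation vector (see [rule_set()]).
#' @return total interaction count (one per prediction-feedback pair).
#' @export
q_learning_count <- function(rule) {
  rule <- rule_set(rule)
  n <- length(rule)
  Q <- matrix(0, n, n)
  count <- 0L
  for (s in seq_len(n)) {
    repeat {
      a <- which.max(Q[s, ])        # greedy, lowest index on ties
      count <- count + 1L
      if (a == rule[s]) {
        Q[s, a] <- Q[s, a] + 1
        break
      }
      Q[s, a] <- Q[s, a] - 1
    }
  }
  count
}

#' Elimination (rank-sum) training count for one rule
#'
#' Abstract counting model equivalent to the spiking interaction loop: states
#' are trained to criterion in `state_order`; the cost of a state is one plus
#' the number of not-yet-learned intentions probed before the correct one
#' (candidates in ascending index order), and an intention, once learned,
#' is excluded from every later candidate list - the behavioural signature
#' of the column-wise depression issued on positive reward.
#'
#' @param rule permutation vector (see [rule_set()]).
#' @param state_order order in which states are trained (default ascending).
#' @return total interaction count.
#' @export
rank_sum_count <- function(rule, state_order = seq_along(rule)) {
  rule <- rule_set(rule)
  n <- length(rule)
  if (!identical(sort(as.integer(state_order)), seq_len(n))) {
    stop("state_order must be a permutation of 1..N")
  }
  learned <- logical(n)
  total <- 0L
  for (s in state_order) {
    candidates <- which(!learned)
    total <- total + match(rule[s], candidates)
    learned[rule[s]] <- TRUE
  }
  total
}

#' Training-count statistics over the rule space
#'
#' Computes min, max and mode (ties resolved by their mean) of the
#' elimination-model training counts over intention-action rule sets:
#' exhaustively over all `N!` permutations (allowed up to `N = 10`), or over
#' a seeded Monte-Carlo sample for larger `N`. The exhaustive enumeration
#' runs in compiled code; [rank_sum_count()] is the reference definition.
#'
#' @param n number of intentions.
#' @param method `"exhaustive"` or `"sampled"`.
#' @param n_samples number of sampled rules when `method = "sampled"`.
#' @param seed integer seed for sampling.
#' @return object of class `training_distribution` with fields `n`,
#'   `n_rules` (`N!`), `n_evaluated`, `min`, `max`, `mode`, `method` and the
#'   count frequency `table`.
#' @export
distribution_over_rules <- function(n, method = c("exhaustive", "sampled"),
                                    n_samples = 1e5, seed = 1L) {
  method <- match.arg(method)
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (method == "exhaustive") {
    if (n > 10) {
      stop("exhaustive enumeration refused for n > 10 (", n,
           "! rules); use method = \"sampled\"")
    }
    counts <- rule_count_all_cpp(n, "ranksum")
    n_eval <- length(counts)
  } else {
    set.seed(seed)
    perms <- vapply(seq_len(n_samples), function(i) sample.int(n),
                    integer(n))
    counts <- rule_count_perms_cpp(matrix(perms, nrow = n), "ranksum")
    n_eval <- n_samples
  }
  tab <- table(counts)
  structure(
    list(
      n = n,
      n_rules = factorial(n),
      n_evaluated = n_eval,
      min = min(counts),
      max = max(counts),
      mode = mode_tied_mean(counts),
      method = method,
      table = tab
    ),
    class = "training_distribution"
  )
}

#' @export
print.training_distribution <- function(x, ...) {
  cat(sprintf(
    "<training_distribution> N = %d (%s over %s rules)\n  min %d | mode %s | max %d\n",
    x$n, x$method, format(x$n_evaluated, big.mark = ","),
    x$min, format(x$mode), x$max
  ))
  invisible(x)
}

#' Mode with tied modes resolved by their mean
#'
#' @param x integer-valued vector of counts.
#' @return the most frequent value; when several values tie for most
#'   frequent, the mean of the tied values.
#' @export
mode_tied_mean <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab)[tab == max(tab)])
  mean(vals)
}

#' Training-cost advantage over the Q-learning baseline
#'
#' The baseline needs `N(N+1)/2` interactions for every rule; the
#' elimination model's count distribution over rules is symmetric, so its
#' mode equals its mean `(N + N(N+1)/2) / 2`. The advantage is their
#' difference, which reduces to the closed form `(N^2 - N) / 4`.
#'
#' @param n number of intentions.
#' @return data frame with `n`, `train_q`, `train_biip` (the elimination
#'   model's modal count), `train_improve` and the `closed_form` value.
#' @export
improvement_formula <- function(n) {
  stopifnot(n >= 1)
  train_q <- q_learning_count(seq_len(n))
  train_biip <- (n + n * (n + 1) / 2) / 2
  data.frame(
    n = n,
    train_q = train_q,
    train_biip = train_biip,
    train_improve = train_q - train_biip,
    closed_form = (n^2 - n) / 4
  )
}

#' Rule-space comparison table: baseline vs the elimination model
#'
#' For each `N` in `n_range`, enumerates the rule space exhaustively (all
#' `N!` rules), runs the reconstructed Q-learning baseline across rules to
#' verify its rule-invariance, and reports number of rules, the baseline
#' count, and the mode/min/max of the elimination-model counts.
#'
#' @param n_range integers, each at most 10.
#' @return data frame with one row per statistic and one column per `N`,
#'   rows: `Number of rules`, `Q-learning method`,
#'   `The proposed model (Mode)`, `(Min)`, `(Max)`.
#' @export
comparison_table <- function(n_range = 1:9) {
  stopifnot(all(n_range >= 1), all(n_range <= 10))
  cols <- lapply(n_range, function(n) {
    dist <- distribution_over_rules(n, "exhaustive")
    q_counts <- rule_count_all_cpp(n, "qlearn")
    if (length(unique(q_counts)) != 1L) {
      stop("Q-learning baseline count is not rule-invariant at N = ", n)
    }
    c(
      `Number of rules` = factorial(n),
      `Q-learning method` = q_counts[1],
      `The proposed model (Mode)` = dist$mode,
      `The proposed model (Min)` = dist$min,
      `The proposed model (Max)` = dist$max
    )
  })
  out <- as.data.frame(cols)
  names(out) <- as.character(n_range)
  out <- cbind(statistic = rownames(out), out)
  rownames(out) <- NULL
  out
}
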