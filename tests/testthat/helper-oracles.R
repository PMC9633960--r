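# Independent reference implementations used as oracles. These deliberately
# re-derive results from first principles (scalar arithmetic, direct
# enumeration) rather than calling the package's vectorised code paths.

# Scalar forward-Euler reference for the two-variable quadratic neuron.
ref_euler_step <- function(v, u, a, b, c, d, I, dt) {
  v_new <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u_new <- u + dt * (a * (b * v - u))
  fired <- v_new >= 30
  if (fired) {
    u_new <- u_new + d
    v_new <- c
  }
  list(v = v_new, u = u_new, fired = fired)
}

# Integrate from rest under constant current; return the step index of the
# first spike (NA if none within n_steps).
ref_first_spike <- function(a, b, c, d, I, dt, n_steps) {
  v <- -65; u <- b * -65
  for (k in seq_len(n_steps)) {
    st <- ref_euler_step(v, u, a, b, c, d, I, dt)
    v <- st$v; u <- st$u
    if (st$fired) return(k)
  }
  NA_integer_
}

# Elimination-count oracle written independently of rank_sum_count():
# explicit simulation of probing candidates in ascending order.
ref_elimination_count <- function(rule, state_order = seq_along(rule)) {
  n <- length(rule)
  learned <- rep(FALSE, n)
  total <- 0L
  for (s in state_order) {
    for (j in seq_len(n)) {
      if (learned[j]) next
      total <- total + 1L
      if (j == rule[s]) break
    }
    learned[rule[s]] <- TRUE
  }
  total
}

# All permutations of 1..n (n small), via recursive construction.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- as.integer(append(p, n, after = pos - 1L))
    }
  }
  out
}
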