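test_that("configuration defaults carry the published constants", {
  cfg <- intent_config()
  expect_identical(cfg$stdp,
                   list(A_plus = 0.777, A_minus = -0.237,
                        tau_plus = 16.8, tau_minus = -33.7))
  expect_identical(cfg$neuron_params$StrD1[c("a", "b")], list(a = 0.01, b = 0.01))
  expect_identical(cfg$neuron_params$StrD2[c("a", "b")], list(a = 0.1, b = 0.5))
  expect_identical(cfg$neuron_params$other[c("a", "b")], list(a = 0.02, b = 0.6))
  expect_identical(cfg$neuron_params$other[c("c", "d")], list(c = -65, d = 8))
})

test_that("YAML configuration round-trips with precedence CLI > file > default", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_intentions: 6", "w0: 4.5", "A_plus: 0.9", "seed: 3"), path)
  cfg <- load_config(path)
  expect_identical(cfg$n_intentions, 6L)
  expect_identical(cfg$w0, 4.5)
  expect_identical(cfg$stdp$A_plus, 0.9)
  expect_identical(cfg$stdp$A_minus, -0.237)      # untouched default
  cfg2 <- load_config(path, overrides = list(w0 = 7))
  expect_identical(cfg2$w0, 7)
  writeLines("not_a_knob: 1", path)
  expect_error(load_config(path), "unknown configuration key")
})

test_that("every documented tunable is settable and echoed into the run log", {
  knobs <- list(
    n_intentions = 5L, dt = 0.25, window_ms = 80, drive_current = 25,
    fixed_weight = 40, w0 = 8, weight_floor_frac = 1e-2,
    lag_ltp = -12, lag_ltd = 9, presentation = "sequential", seed = 2L
  )
  cfg <- do.call(intent_config, knobs)
  for (k in names(knobs)) expect_identical(cfg[[k]], knobs[[k]])
  log <- withr::local_tempfile(fileext = ".jsonl")
  run_table1(1, 2, log = log, config = cfg)
  entry <- jsonlite::fromJSON(readLines(log)[1])
  for (k in setdiff(names(knobs), "seed")) {
    expect_equal(entry[[k]], unname(unlist(knobs[[k]])),
                 ignore_attr = TRUE)
  }
  expect_true(all(c("A_plus", "A_minus", "tau_plus", "tau_minus",
                    "timestamp") %in% names(entry)))
})

test_that("table reproduction passes its closed-form checks and writes stable CSV", {
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  res <- run_table1(1, 6, out = out1)
  expect_true(all(res$checks))
  expect_equal(as.numeric(res$table[["6"]]), c(720, 21, 13.5, 6, 21))
  run_table1(1, 6, out = out2)
  expect_identical(readLines(out1), readLines(out2))  # byte-identical reruns

  ext <- withr::local_tempfile(fileext = ".json")
  res2 <- run_table1(1, 3, extended_out = ext, extended_range = 1:50)
  js <- jsonlite::fromJSON(ext)
  expect_identical(nrow(js), 50L)
  expect_equal(js$improvement, (js$n^2 - js$n) / 4)
  expect_equal(js$q_learning - js$model_mode, js$improvement)
})

test_that("sampled table mode stays near the closed form", {
  res <- run_table1(12, 12, mode = "sampled", n_samples = 5e3, seed = 1)
  expect_true(all(res$checks))
  expect_lte(abs(as.numeric(res$table[3, "12"]) - 45), 1)
})

test_that("rule-change experiment reports unchanged states at unit cost", {
  dir <- withr::local_tempdir()
  res <- run_rule_change(c(1, 2, 3, 4), c(2, 1, 3, 4), out_dir = dir)
  expect_true(res$unchanged_cost_one)
  expect_identical(res$per_state$relearn_interactions[3:4], c(1L, 1L))
  expect_true(all(res$per_state$abandoned_old_after[1:2] >= 1))
  expect_true(file.exists(file.path(dir, "weights_before.csv")))
  W_before <- read_weights_csv(file.path(dir, "weights_before.csv"))
  expect_identical(as.integer(apply(W_before, 1, which.max)), c(1L, 2L, 3L, 4L))
  W_after <- read_weights_csv(file.path(dir, "weights_after.csv"))
  expect_identical(as.integer(apply(W_after, 1, which.max)), c(2L, 1L, 3L, 4L))
  expect_error(run_rule_change(c(1, 2), c(2, 1, 3)), "same number")
})

test_that("gesture demonstration runs end to end and logs its outcome", {
  out <- withr::local_tempfile(fileext = ".csv")
  log <- withr::local_tempfile(fileext = ".jsonl")
  res <- run_gesture_demo(noise = 0.05, batches = 3, seed = 1, out = out,
                          log = log)
  curve <- utils::read.csv(out)
  expect_equal(curve$accuracy, res$accuracy, tolerance = 1e-12)
  done <- jsonlite::fromJSON(readLines(log)[2])
  expect_equal(done$final_accuracy, res$accuracy[3])
})
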