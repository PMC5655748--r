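test_that("truth tables derive from the scenario structures", {
  tt <- truth_tables()
  # scenarios whose generating equations contain an X -> Y effect
  expect_setequal(tt$mr_true_scenarios, c("b", "d", "g", "i"))
  # complete mediation with no further genotype-outcome link
  expect_setequal(tt$cit_true_scenarios, c("b", "i"))
  expect_identical(unname(tt$correct_model[c("h", "i", "j", "k", "l")]),
                   c("a", "b", "c", "m", "n"))
  expect_identical(unname(tt$correct_model[letters[1:7]]), letters[1:7])
  expect_true(all(is.na(tt$sem_correct[c("d", "e", "k", "l")])))
  expect_identical(unname(tt$buf_correct[c("a", "b", "c", "k", "l")]),
                   c("DD", "DI", "ID", "DU", "UD"))
  expect_true(all(is.na(tt$buf_correct[c("d", "e", "f", "g")])))
})

test_that("a benchmark run is reproducible bit-for-bit and its outcome
           proportions are coherent", {
  run1 <- run_scenario("b", methods = c("mr", "sem", "buf", "bnlearn"),
                       n_reps = 30, base_seed = 77)
  run2 <- run_scenario("b", methods = c("mr", "sem", "buf", "bnlearn"),
                       n_reps = 30, base_seed = 77)
  expect_identical(run1$methods, run2$methods)
  for (m in c("sem", "buf", "bnlearn")) {
    s <- run1$methods[[m]]
    expect_equal(s$correct_rate + s$incorrect_rate + s$tie_rate +
                   s$failure_rate, 1)
    expect_true(all(c(s$correct_rate, s$failure_rate) >= 0))
  }
  expect_true(run1$methods$mr$detection_rate >= 0 &&
                run1$methods$mr$detection_rate <= 1)
  df <- as.data.frame(run1)
  expect_setequal(unique(df$method), c("mr", "sem", "buf", "bnlearn"))
  expect_true(all(df$n_reps == 30))
})

test_that("scenarios without a testable correct model report selection
           distributions instead of a correctness rate", {
  run <- run_scenario("k", methods = "sem", n_reps = 20, base_seed = 5)
  s <- run$methods$sem
  expect_true(is.na(s$correct_rate))
  expect_gt(length(s$selected_freq), 0)
  expect_equal(sum(s$selected_freq), 1)
})

test_that("parameter sweeps vary only the requested parameter", {
  sw <- run_sweep("zeta", c(0.5, 2), "h", methods = "sem", n_reps = 10,
                  base_seed = 9)
  expect_length(sw$summaries, 2L)
  expect_equal(sw$summaries[[1]]$spec$zeta, 0.5)
  expect_equal(sw$summaries[[2]]$spec$zeta, 2)
  expect_equal(sw$summaries[[1]]$spec$alpha, 1)
})

test_that("the mean-score matrix artifact has the reference layout", {
  res <- lapply(c("a", "b"), function(s)
    run_scenario(s, methods = c("sem", "buf", "deal"), n_reps = 8,
                 base_seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  tab <- summarize_table2(res, out_csv = csv, out_json = jsn)
  expect_equal(dim(tab$sem$mean_score), c(5L, 2L))
  expect_equal(dim(tab$buf$mean_score), c(9L, 2L))
  expect_equal(dim(tab$deal$mean_score), c(12L, 2L))
  expect_identical(colnames(tab$sem$mean_score), c("a", "b"))
  expect_identical(unname(tab$sem$correct), c("a", "b"))
  expect_true(file.exists(csv) && file.exists(jsn))
  got <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(sum(got$method == "buf"), 9L)
  # empty input produces an empty artifact, not an error
  empty <- summarize_table2(list(), out_csv = csv)
  expect_length(empty, 0L)
  expect_equal(nrow(utils::read.csv(csv)), 0L)
})

test_that("method failures are counted, never fatal", {
  # monomorphic genotypes (maf ~ 0) break every method's preconditions
  run <- run_scenario("b", methods = c("mr", "sem"), n_reps = 5,
                      base_seed = 1, spec_args = list(maf = 1e-9, n = 50))
  expect_equal(run$methods$mr$detection_rate, 0)
  expect_equal(run$methods$mr$failure_rate, 1)
  expect_equal(run$methods$sem$failure_rate, 1)
})
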