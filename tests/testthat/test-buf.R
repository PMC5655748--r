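test_that("nine distinct partitions exist with the documented model aliases", {
  p <- buf_partitions()
  expect_equal(nrow(p), 9L)
  expect_equal(anyDuplicated(p$partition), 0L)
  expect_setequal(p$partition[!is.na(p$alias)],
                  c("DD", "DI", "ID", "DU", "UD", "UU"))
  expect_equal(p$alias[p$partition == "DI"], "b")
  expect_equal(p$alias[p$partition == "DU"], "m")
})

test_that("partitions without a directly associated trait carry log-BF zero,
           and relabelling x and y transposes the table", {
  for (i in 1:10) {
    d <- rand_triplet(n = 70, seed = 400 + i)
    r <- buf_bf(d$g, d$x, d$y)
    expect_identical(unname(r$log10_bf[c("UU", "UI", "IU", "II")]),
                     rep(0, 4))
    rt <- buf_bf(d$g, d$y, d$x)
    expect_equal(r$log10_bf[["DU"]], rt$log10_bf[["UD"]])
    expect_equal(r$log10_bf[["DI"]], rt$log10_bf[["ID"]])
    # factorization: the two-trait partition is the product of its
    # marginal and conditional single-trait factors
    expect_equal(r$log10_bf[["DD"]],
                 r$log10_bf[["DI"]] + r$log10_bf[["UD"]],
                 tolerance = 1e-10)
  }
  expect_error(buf_bf(rbinom(30, 2, .3), rnorm(30), rnorm(30),
                      sigma_a_grid = c(0.1, -1)), "positive")
  expect_error(buf_bf(rbinom(30, 2, .3), rep(1, 30), rnorm(30)), "degenerate")
})

test_that("under the global null the conjugate Bayes factor penalises
           genotype inclusion on average", {
  spec0 <- scenario_spec("b", alpha = 0, gamma = 0)
  lbf <- matrix(NA_real_, 500, 5)
  for (r in 1:500) {
    d <- simulate_triplet(spec0, seed = triplet_seed(23, "null", r))
    lbf[r, ] <- buf_bf(d)$log10_bf[c("DI", "DU", "DD", "ID", "UD")]
  }
  expect_true(all(colMeans(lbf) <= 0))
})

test_that("selection demands a unique argmax", {
  d <- rand_triplet(n = 60, seed = 5)
  r <- buf_bf(d$g, d$x, d$y)
  expect_true(buf_select(r, r$selected))
  # aliases are accepted
  alias <- buf_partitions()$alias[match(r$selected, buf_partitions()$partition)]
  if (!is.na(alias)) expect_true(buf_select(r, alias))
  expect_false(buf_select(r, setdiff(c("DI", "ID"), r$selected)[1]))
  # an all-tie table selects nothing
  r$log10_bf[] <- 0; r$tie_flag <- TRUE
  expect_false(buf_select(r, "DI"))
  expect_error(buf_select(r, "QQ"), "unknown partition")
})
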