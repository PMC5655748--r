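test_that("exactly the 12 admissible DAGs are enumerated", {
  dags <- enumerate_dags()
  expect_length(dags, 12L)
  # brute force: 2 x 2 x 3 edge configurations, all acyclic, none into G
  combos <- expand.grid(gx = c(FALSE, TRUE), gy = c(FALSE, TRUE),
                        xy = c("none", "xy", "yx"), stringsAsFactors = FALSE)
  sig <- function(gx, gy, xy)
    paste(sort(c(if (gx) "G->X", if (gy) "G->Y",
                 if (xy == "xy") "X->Y", if (xy == "yx") "Y->X")),
          collapse = ",")
  expected <- apply(combos, 1, function(r)
    sig(as.logical(r["gx"]), as.logical(r["gy"]), r["xy"]))
  got <- vapply(dags, function(d) paste(sort(d$edges), collapse = ","), "")
  expect_setequal(unname(got), expected)
  expect_setequal(dags$d$edges, c("G->X", "G->Y", "X->Y"))
  expect_false(any(grepl("->G", unlist(lapply(dags, `[[`, "edges")))))
})

test_that("Markov-equivalent structures score identically under both
           scorers", {
  for (i in 1:25) {
    d <- rand_triplet(n = 90, seed = 500 + i)
    for (fn in list(function(m) score_dag_bic_cg(m, d$g, d$x, d$y),
                    function(m) score_dag_deal(m, d$g, d$x, d$y, iss = 6))) {
      expect_equal(as.numeric(fn("d")), as.numeric(fn("e")), tolerance = 1e-8)
      expect_equal(as.numeric(fn("xy")), as.numeric(fn("yx")), tolerance = 1e-8)
    }
  }
})

test_that("the network score decomposes over node families", {
  d <- rand_triplet(n = 120, seed = 61)
  for (kind in c("bic_cg", "deal")) {
    tab <- bn_score(d$g, d$x, d$y, score = kind)
    s_b <- if (kind == "bic_cg") score_dag_bic_cg("b", d$g, d$x, d$y)
           else score_dag_deal("b", d$g, d$x, d$y)
    bn_b <- attr(s_b, "by_node")
    expect_equal(as.numeric(s_b), sum(bn_b))
    expect_equal(tab$scores[["b"]], as.numeric(s_b))
    # the y family (parent x only) is shared between models b and xy
    s_xy <- if (kind == "bic_cg") score_dag_bic_cg("xy", d$g, d$x, d$y)
            else score_dag_deal("xy", d$g, d$x, d$y)
    expect_equal(bn_b[["y"]], attr(s_xy, "by_node")[["y"]])
    # and the g family is identical across all structures
    expect_equal(bn_b[["g"]], attr(s_xy, "by_node")[["g"]])
  }
})

test_that("a true genotype-trait edge improves the penalized score on
           average", {
  diffs <- vapply(1:200, function(r) {
    d <- simulate_triplet(scenario_spec("k", n = 300), # G->X only (plus E)
                          seed = triplet_seed(29, "k", r))
    score_dag_bic_cg("m", d) - score_dag_bic_cg("null", d)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("selection is equivalence-class aware and validates its input", {
  d <- simulate_triplet(scenario_spec("h", n = 2000), seed = 71)
  tab <- bn_score(d, score = "bic_cg")
  if (any(c("d", "e") %in% tab$selected))
    expect_setequal(tab$selected, c("d", "e"))
  expect_error(bn_score(d, score = "deal", iss = -1), "iss")
  expect_error(score_dag_bic_cg("zz", d), "unknown DAG")
})

test_that("the imaginary sample size governs prior weight and can flip the
           selected structure", {
  picks <- vapply(c(0.1, 6, 1000), function(iss) {
    sel <- vapply(1:30, function(r) {
      d <- simulate_triplet(scenario_spec("a"), seed = triplet_seed(3, "a", r))
      paste(bn_score(d, score = "deal", iss = iss)$selected, collapse = "/")
    }, "")
    names(sort(table(sel), decreasing = TRUE))[1]
  }, "")
  expect_gt(length(unique(picks)), 1L)
  # scores themselves must respond to the prior weight
  d <- simulate_triplet(scenario_spec("a", n = 200), seed = 5)
  expect_false(isTRUE(all.equal(score_dag_deal("a", d, iss = 1),
                                score_dag_deal("a", d, iss = 50))))
})

test_that("sparse genotype levels are pooled rather than failing", {
  set.seed(9)
  g <- c(rbinom(198, 1, 0.4), 2L, 2L)  # two observations with G = 2
  x <- rnorm(200, g); y <- rnorm(200, x)
  tab <- bn_score(g, x, y, score = "bic_cg")
  expect_true(tab$pooled)
  expect_true(all(is.finite(tab$scores)))
})
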