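test_that("default specifications carry the study-wide parameter values", {
  for (s in scenario_ids()) {
    sp <- default_spec(s)
    expect_equal(sp$alpha, 1)
    expect_equal(sp$beta, 1)
    expect_equal(sp$gamma, 1)
    expect_equal(sp$delta, 1)
    expect_equal(sp$zeta, 1)
    expect_equal(sp$mu_x, 10)
    expect_equal(sp$mu_y, 10)
    expect_equal(sp$sigma_x, 0.3)
    expect_equal(sp$sigma_y, 0.3)
    expect_equal(sp$sigma_e, 0.3)
    expect_equal(sp$maf, 0.1)
    expect_equal(sp$n, 1000L)
  }
  expect_error(default_spec("z"), "unknown scenario")
  expect_error(scenario_spec("a", maf = 0.6), "maf")
  expect_error(scenario_spec("a", sigma_x = 0), "positive")
  expect_error(scenario_spec("a", n = 1), "n must be")
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  expect_error(simulate_genotypes(0, 0.1), "positive")
  expect_error(simulate_genotypes(10, 0), "maf")
  expect_error(simulate_genotypes(10, 0.7), "maf")

  # degenerate allele frequency: essentially no minor alleles
  expect_equal(simulate_genotypes(4, 1e-12, seed = 1), rep(0L, 4))

  n <- 1e6; q <- 0.1
  g <- simulate_genotypes(n, q, seed = 42)
  expect_true(all(g %in% 0:2))
  p_exp <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  p_obs <- tabulate(g + 1L, 3L) / n
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_true(all(abs(p_obs - p_exp) < 3 * se))
  # binomial(2, q) variance, 2q(1-q) = 0.18
  expect_equal(var(g), 2 * q * (1 - q), tolerance = 0.01)
})

test_that("same seed reproduces a replicate bit-for-bit, substreams differ", {
  for (s in c("b", "h")) {
    sp <- scenario_spec(s, n = 200)
    d1 <- simulate_triplet(sp, seed = triplet_seed(7, s, 3))
    d2 <- simulate_triplet(sp, seed = triplet_seed(7, s, 3))
    expect_identical(d1$g, d2$g)
    expect_identical(d1$x, d2$x)
    expect_identical(d1$y, d2$y)
    d3 <- simulate_triplet(sp, seed = triplet_seed(7, s, 4))
    expect_false(identical(d1$x, d3$x))
  }
  expect_false(triplet_seed(7, "a", 1) == triplet_seed(7, "b", 1))
  expect_false(triplet_seed(7, "a", 1) == triplet_seed(8, "a", 1))
})

test_that("the latent confounder is generated only for scenarios h-l, and
           never exposed to the methods", {
  for (s in scenario_ids()) {
    d <- simulate_triplet(scenario_spec(s, n = 50), seed = 1)
    if (s %in% c("h", "i", "j", "k", "l")) {
      expect_true(is.numeric(d$e) && length(d$e) == 50)
    } else {
      expect_null(d$e)
    }
    expect_named(as.data.frame(d), c("g", "x", "y"))
  }
})

test_that("sample moments match the closed-form covariance of every scenario", {
  n <- 1e5
  for (s in scenario_ids()) {
    sp <- scenario_spec(s, n = n)
    d <- simulate_triplet(sp, seed = triplet_seed(123, s, 1))
    Z <- cbind(g = d$g, x = d$x, y = d$y)
    S_obs <- cov(Z)
    S_exp <- oracle_cov(sp)
    # distribution-free standard error of each covariance entry (the
    # genotype's fourth moment is far from Gaussian)
    Zc <- sweep(Z, 2, colMeans(Z))
    se <- sqrt(outer(1:3, 1:3, Vectorize(function(i, j)
      var(Zc[, i] * Zc[, j]))) / n)
    expect_true(all(abs(S_obs - S_exp) < 4 * se),
                info = paste("scenario", s))
  }
  # spot values implied by the generating equations:
  # corr(G, Y) = 1/sqrt(2) under (b); cov(X, Y) = 0.27 under (h)
  db <- simulate_triplet(scenario_spec("b", n = n), seed = 9)
  expect_equal(cor(db$g, db$y), sqrt(0.5), tolerance = 0.01)
  dh <- simulate_triplet(scenario_spec("h", n = n), seed = 9)
  expect_equal(cov(dh$x, dh$y), 0.27, tolerance = 4 * sqrt(2) * 0.36 / sqrt(n))
})

test_that("with all effects zero the traits decorrelate", {
  d <- simulate_triplet(
    scenario_spec("b", alpha = 0, gamma = 0, n = 1e5), seed = 3)
  expect_lt(abs(cor(d$g, d$x)), 0.02)
  expect_lt(abs(cor(d$x, d$y)), 0.02)
})

test_that("replicates round-trip through the delimited writer", {
  d <- simulate_triplet(scenario_spec("c", n = 40), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_triplet(d, f)
  # no latent column on disk, header present
  expect_identical(strsplit(readLines(f, 1), "\t")[[1]], c("g", "x", "y"))
  r <- read_triplet(f)
  expect_equal(r$g, d$g)
  expect_equal(r$x, d$x, tolerance = 1e-12)
  expect_equal(r$y, d$y, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$scenario_id, "c")
  expect_equal(side$seed_record, 5)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g\tx\ty", "3\t1.0\t2.0"), bad)
  expect_error(read_triplet(bad), "0/1/2")
})
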