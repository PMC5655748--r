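# Independent oracles used across the test files.
#
# The closed-form moments are computed here by linear path algebra over the
# full variable set (g, e, x, y), independently of the simulator's sequential
# sampling; the structural tables are written out by hand from the generating
# equations rather than queried from the package.

oracle_structure <- list(
  a = list(x = c(g = "alpha"),              y = c(g = "beta")),
  b = list(x = c(g = "alpha"),              y = c(x = "gamma")),
  c = list(x = c(y = "gamma"),              y = c(g = "beta")),
  d = list(x = c(g = "alpha"),              y = c(g = "beta", x = "gamma")),
  e = list(x = c(g = "alpha", y = "delta"), y = c(g = "beta")),
  f = list(x = c(g = "alpha", y = "delta"), y = c()),
  g = list(x = c(),                         y = c(g = "beta", x = "gamma")),
  h = list(x = c(g = "alpha", e = "zeta"),  y = c(g = "beta", e = "zeta")),
  i = list(x = c(g = "alpha", e = "zeta"),  y = c(x = "gamma", e = "zeta")),
  j = list(x = c(y = "delta", e = "zeta"),  y = c(g = "beta", e = "zeta")),
  k = list(x = c(g = "alpha", e = "zeta"),  y = c(e = "zeta")),
  l = list(x = c(e = "zeta"),               y = c(g = "beta", e = "zeta"))
)

# population covariance of (g, x, y) implied by a scenario spec:
# Sigma = (I - B)^-1 Psi (I - B)^-T over variable order (g, e, x, y)
oracle_cov <- function(spec) {
  def <- oracle_structure[[spec$scenario_id]]
  vars <- c("g", "e", "x", "y")
  B <- matrix(0, 4, 4, dimnames = list(vars, vars))
  for (v in c("x", "y"))
    for (p in names(def[[v]]))
      B[v, p] <- spec[[def[[v]][[p]]]]
  Psi <- diag(c(2 * spec$maf * (1 - spec$maf), spec$sigma_e^2,
                spec$sigma_x^2, spec$sigma_y^2))
  IB <- solve(diag(4) - B)
  Sigma <- IB %*% Psi %*% t(IB)
  dimnames(Sigma) <- list(vars, vars)
  Sigma[c("g", "x", "y"), c("g", "x", "y")]
}

# small random dataset with a polymorphic genotype and arbitrary trait
# dependence, for invariance/identity checks
rand_triplet <- function(n = 80, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    g <- rbinom(n, 2L, runif(1, 0.15, 0.5))
    if (length(unique(g)) >= 2) break
  }
  bx <- rnorm(1); by <- rnorm(1); bxy <- rnorm(1)
  x <- rnorm(n, bx * g, runif(1, 0.5, 2))
  y <- rnorm(n, by * g + bxy * x, runif(1, 0.5, 2))
  list(g = g, x = x, y = y)
}

# numeric maximum likelihood for a path model: direct minimisation of the
# covariance discrepancy F_ML over the five free parameters, bypassing the
# package's per-equation closed form
sem_numeric_ml <- function(model_id, d) {
  defs <- list(
    a = list(x = "g",         y = "g"),
    b = list(x = "g",         y = "x"),
    c = list(x = "y",         y = "g"),
    f = list(x = c("g", "y"), y = character()),
    g = list(x = character(), y = c("g", "x"))
  )
  def <- defs[[model_id]]
  S <- cov(cbind(g = d$g, x = d$x, y = d$y))
  n <- length(d$g)
  slots <- list()
  for (v in c("x", "y")) for (p in def[[v]]) slots[[length(slots) + 1]] <- c(v, p)
  build_sigma <- function(th) {
    B <- matrix(0, 3, 3, dimnames = list(c("g", "x", "y"), c("g", "x", "y")))
    for (i in seq_along(slots)) B[slots[[i]][1], slots[[i]][2]] <- th[i]
    Psi <- diag(exp(th[length(slots) + 1:3]))
    IB <- solve(diag(3) - B)
    IB %*% Psi %*% t(IB)
  }
  f_ml <- function(th) {
    tryCatch({
      Sigma <- build_sigma(th)
      ld <- determinant(Sigma, TRUE)
      if (ld$sign <= 0 || !is.finite(ld$modulus)) return(1e10)
      v <- as.numeric(ld$modulus) - as.numeric(determinant(S, TRUE)$modulus) +
        sum(diag(S %*% solve(Sigma))) - 3
      if (!is.finite(v)) 1e10 else v
    }, error = function(e) 1e10)
  }
  th0 <- c(rep(0.5, length(slots)), log(diag(S)))
  opt <- optim(th0, f_ml, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  Sigma <- build_sigma(opt$par)
  list(f_ml = opt$value,
       loglik = -(n - 1) / 2 *
         (as.numeric(determinant(Sigma, TRUE)$modulus) +
            sum(diag(S %*% solve(Sigma))) + 3 * log(2 * pi)))
}
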