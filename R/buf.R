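## Bayesian partition framework: classify each trait as Unassociated,
## Directly or Indirectly associated with the genotype, and compare the nine
## resulting partitions by Bayes factors against the all-unassociated null.

#' The nine genotype-association partitions
#'
#' Each of X and Y is classed as `U` (unassociated with G), `D` (directly
#' associated) or `I` (indirectly associated, i.e. associated only through
#' the other trait), giving nine partitions.  Five coincide with causal
#' models of the benchmark: `DD` = (a), `DI` = (b), `ID` = (c), `DU` = (m,
#' one arrow G to X), `UD` = (n, one arrow G to Y); `UU` is the reference
#' null.
#'
#' @return A data frame with columns `partition` (two-letter code, X class
#'   then Y class), `x_class`, `y_class` and `alias` (model letter or `NA`).
#' @export
buf_partitions <- function() {
  cls <- c("U", "D", "I")
  grid <- expand.grid(x_class = cls, y_class = cls,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$partition <- paste0(grid$x_class, grid$y_class)
  alias <- c(DD = "a", DI = "b", ID = "c", DU = "m", UD = "n", UU = "null")
  grid$alias <- unname(alias[grid$partition])
  grid[, c("partition", "x_class", "y_class", "alias")]
}

## log (natural) Bayes factor for including g in a Gaussian linear regression
## of z on covariates C, with flat priors on intercept/covariates, Jeffreys
## prior on the residual variance and N(0, sigma_a^2 * sigma^2) on the
## per-allele g coefficient; averaged over the sigma_a grid.
log_bf1 <- function(z, g, C = NULL, sigma_a_grid) {
  n <- length(z)
  X0 <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  zt <- stats::lm.fit(X0, z)$residuals
  gt <- stats::lm.fit(X0, g)$residuals
  m <- n - ncol(X0)
  gg <- sum(gt^2); zz <- sum(zt^2)
  if (gg <= 0 || zz <= 0) return(0)  # degenerate: no evidence either way
  r2 <- sum(gt * zt)^2 / (gg * zz)
  lbf <- vapply(sigma_a_grid, function(s) {
    cc <- s^2 * gg
    -0.5 * log1p(cc) - (m / 2) * log1p(-(cc / (1 + cc)) * r2)
  }, numeric(1))
  ## average Bayes factors (not logs) uniformly over the grid
  mx <- max(lbf)
  mx + log(mean(exp(lbf - mx)))
}

#' Bayes factors for the nine genotype-association partitions
#'
#' For each partition the joint density factorises as p(U variables) x
#' p(D variables | U variables, G) x p(I variables | D, U variables), and the
#' Bayes factor against the all-unassociated partition reduces to a product
#' of single-response regression Bayes factors testing inclusion of G, one
#' per directly associated trait, with the U trait (if any) as a covariate
#' and with indirectly associated traits contributing a factor of one.
#' Concretely (log10 scale): `DI` = BF1(X; test G), `DU` = BF1(X; covariate
#' Y, test G), `DD` = BF1(X; test G) x BF1(Y; covariate X, test G), and
#' symmetrically for Y; partitions with no D trait have Bayes factor exactly
#' one.
#'
#' BF1 is the conjugate Gaussian-regression Bayes factor with a zero-centred
#' normal prior on the per-allele genotype effect, scale `sigma_a` x residual
#' standard deviation; traits are standardised to unit variance beforehand so
#' the scale is interpretable across traits.  Bayes factors are averaged
#' uniformly over `sigma_a_grid`; the default is the single moderate scale
#' 0.1 (see the package vignette for its calibration).  Deterministic.
#'
#' @inheritParams mr_test
#' @param sigma_a_grid Positive prior scales for the standardized per-allele
#'   effect; Bayes factors are averaged uniformly over the grid.
#' @return An object of class `buf_result`: `log10_bf` (named vector over
#'   the nine partition codes), `selected`, `tie_flag`, `sigma_a_grid`.
#' @examples
#' d <- simulate_triplet(scenario_spec("b"), seed = 1)
#' buf_bf(d)
#' @export
buf_bf <- function(g, x = NULL, y = NULL, sigma_a_grid = 0.1) {
  d <- resolve_triplet(g, x, y)
  if (!is.numeric(sigma_a_grid) || length(sigma_a_grid) == 0 ||
      any(sigma_a_grid <= 0))
    stop("sigma_a_grid must be a nonempty vector of positive scales",
         call. = FALSE)
  sx <- stats::sd(d$x); sy <- stats::sd(d$y)
  if (!is.finite(sx) || sx <= 0 || !is.finite(sy) || sy <= 0)
    stop("degenerate data: a trait has zero variance", call. = FALSE)
  xs <- d$x / sx; ys <- d$y / sy
  gnum <- d$g

  bf_x_marg <- log_bf1(xs, gnum, NULL, sigma_a_grid)
  bf_y_marg <- log_bf1(ys, gnum, NULL, sigma_a_grid)
  bf_x_cond <- log_bf1(xs, gnum, matrix(ys, ncol = 1), sigma_a_grid)
  bf_y_cond <- log_bf1(ys, gnum, matrix(xs, ncol = 1), sigma_a_grid)

  ln10 <- log(10)
  lbf <- c(UU = 0, UI = 0, IU = 0, II = 0,
           DI = bf_x_marg,
           DU = bf_x_cond,
           DD = bf_x_marg + bf_y_cond,
           ID = bf_y_marg,
           UD = bf_y_cond) / ln10
  part <- buf_partitions()
  lbf <- lbf[part$partition]
  top <- names(lbf)[which.max(lbf)]
  srt <- sort(lbf, decreasing = TRUE)
  structure(list(log10_bf = lbf, selected = top,
                 tie_flag = (srt[1] - srt[2]) < 1e-9,
                 sigma_a_grid = sigma_a_grid),
            class = "buf_result")
}

#' Was the correct partition selected?
#'
#' @param result A [buf_bf()] result.
#' @param correct Partition code (e.g. `"DI"`) or model alias (`"a"`, `"b"`,
#'   `"c"`, `"m"`, `"n"`, `"null"`).
#' @return `TRUE` iff the highest-Bayes-factor partition is unique and equals
#'   `correct`; ties return `FALSE` (with the result's `tie_flag` set).
#' @export
buf_select <- function(result, correct) {
  stopifnot(inherits(result, "buf_result"))
  part <- buf_partitions()
  if (correct %in% part$alias)
    correct <- part$partition[match(correct, part$alias)]
  if (!correct %in% part$partition) stop("unknown partition: ", correct)
  !result$tie_flag && identical(result$selected, correct)
}

#' @export
print.buf_result <- function(x, ...) {
  cat("Genotype-association partition Bayes factors (log10, vs UU)\n")
  part <- buf_partitions()
  ord <- order(x$log10_bf, decreasing = TRUE)
  for (i in ord) {
    al <- part$alias[match(names(x$log10_bf)[i], part$partition)]
    cat(sprintf("  %s%-7s %9.2f%s\n", names(x$log10_bf)[i],
                ifelse(is.na(al), "", paste0(" (", al, ")")),
                x$log10_bf[i],
                ifelse(i == ord[1], "  <- selected", "")))
  }
  if (x$tie_flag) cat("  [tie among top partitions]\n")
  invisible(x)
}
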