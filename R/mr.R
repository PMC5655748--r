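## Mendelian randomisation: single-instrument two-stage least squares.

#' Mendelian randomisation test of X -> Y
#'
#' Uses the SNP genotype G as an instrumental variable for the putative
#' mediator X and tests whether X causally affects Y.  With a single
#' instrument the two-stage least-squares estimate reduces algebraically to
#' the Wald ratio cov(G, Y) / cov(G, X); the standard error and p-value come
#' from the homoskedastic second-stage Wald test of the fitted-X coefficient
#' (normal approximation).
#'
#' The validity of the causal interpretation rests on the usual instrumental
#' variable assumptions: G associates with X, and G affects Y only through X.
#' Under pleiotropy (G affecting both traits directly) the estimator converges
#' to the ratio of the two direct effects and the test will report a spurious
#' "causal" effect -- by design, since this is precisely the failure mode the
#' simulation study measures.
#'
#' @param g Genotype vector (0/1/2), or a `triplet_data`/data frame holding
#'   `g`, `x`, `y`.
#' @param x,y Mediator and outcome vectors (ignored when `g` is a dataset).
#' @param threshold Detection threshold on the p-value (default 0.05).
#' @return An object of class `mr_test`: list with `beta_iv`, `se`,
#'   `p_value`, `detected`, and `flag` (`"ok"`, `"degenerate_instrument"` for
#'   a monomorphic SNP, or `"weak_instrument"` when cov(G, X) is numerically
#'   zero).  Flagged results have `detected = FALSE` and `NA` estimates.
#' @examples
#' d <- simulate_triplet(scenario_spec("b"), seed = 1)
#' mr_test(d)
#' @export
mr_test <- function(g, x = NULL, y = NULL, threshold = 0.05) {
  d <- resolve_triplet(g, x, y)
  if (d$n < 3L) stop("need at least 3 observations", call. = FALSE)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)

  out <- structure(
    list(beta_iv = NA_real_, se = NA_real_, p_value = NA_real_,
         detected = FALSE, threshold = threshold, n = d$n, flag = "ok"),
    class = "mr_test")

  gc_ <- d$g - mean(d$g); xc <- d$x - mean(d$x); yc <- d$y - mean(d$y)
  sgg <- sum(gc_^2)
  if (sgg == 0) {
    out$flag <- "degenerate_instrument"
    return(out)
  }
  sgx <- sum(gc_ * xc)
  sxx <- sum(xc^2)
  ## instrument relevance: cov(g, x) numerically zero relative to the scales
  if (sxx == 0 || abs(sgx) < 1e-12 * sqrt(sgg * sxx)) {
    out$flag <- "weak_instrument"
    return(out)
  }

  beta <- sum(gc_ * yc) / sgx                # Wald ratio == 2SLS
  ## second stage: OLS of y on xhat, xhat = fitted(x ~ g); var(xhat) = sgx^2/sgg
  sxhat <- sgx^2 / sgg
  resid <- yc - beta * (gc_ * sgx / sgg)
  sigma2 <- sum(resid^2) / (d$n - 2)
  se <- sqrt(sigma2 / sxhat)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  out$beta_iv <- beta
  out$se <- se
  out$p_value <- p
  out$detected <- is.finite(p) && p < threshold
  out
}

#' @export
print.mr_test <- function(x, ...) {
  cat("Mendelian randomisation (2SLS, single instrument)\n")
  if (x$flag != "ok") {
    cat("  flagged:", x$flag, "-> no detection\n")
  } else {
    cat(sprintf("  beta_iv = %.4f  (se %.4f),  p = %.3g  [n = %d]\n",
                x$beta_iv, x$se, x$p_value, x$n))
    cat(sprintf("  X -> Y detected at %.3g level: %s\n",
                x$threshold, ifelse(x$detected, "yes", "no")))
  }
  invisible(x)
}
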