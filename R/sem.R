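## Gaussian path models over (G, X, Y): maximum-likelihood fit and lowest-BIC
## selection among the five structures with a testable degree of freedom.

.sem_models <- list(
  a = list(x = "g",          y = "g"),
  b = list(x = "g",          y = "x"),
  c = list(x = "y",          y = "g"),
  f = list(x = c("g", "y"),  y = character()),
  g = list(x = character(),  y = c("g", "x"))
)

#' Identifiers of the testable path models
#' @return `c("a","b","c","f","g")`: the five recursive path structures over
#'   (G, X, Y) with one testable degree of freedom.  The remaining structures
#'   are saturated (df = 0) and carry no goodness-of-fit information, so they
#'   are excluded from BIC comparison.
#' @export
sem_model_ids <- function() names(.sem_models)

#' Fit one Gaussian path model by maximum likelihood
#'
#' Fits a recursive linear-Gaussian path model over (G, X, Y).  For these
#' models (uncorrelated errors, no latent variables) per-equation least
#' squares computed from the sample covariance matrix is the exact maximum
#' likelihood solution.  Model fit is summarised by the covariance-structure
#' discrepancy
#' \deqn{F_{ML} = \log|\Sigma(\hat\theta)| - \log|S| +
#'       \mathrm{tr}(S \Sigma(\hat\theta)^{-1}) - 3,}
#' with `chi_square = (n - 1) * F_ML` (means saturated), `df = 1` for all five
#' models (6 distinct second moments, 5 free parameters) and
#' `bic = chi_square - df * log(n)`.  Lower BIC indicates better fit; a
#' correctly specified model has E\[chi_square\] close to 1, hence mean BIC
#' close to `1 - log(n)`.
#'
#' @param model_id One of [sem_model_ids()].
#' @inheritParams mr_test
#' @return An object of class `sem_fit` with `theta` (path coefficients and
#'   variances), `chi_square`, `df`, `bic`, `loglik`, `n`.
#' @examples
#' d <- simulate_triplet(scenario_spec("a"), seed = 1)
#' sem_fit_model("a", d)
#' @export
sem_fit_model <- function(model_id, g, x = NULL, y = NULL) {
  if (!model_id %in% names(.sem_models))
    stop("model_id must be one of ", paste(sem_model_ids(), collapse = ", "))
  d <- resolve_triplet(g, x, y)
  S <- stats::cov(cbind(g = d$g, x = d$x, y = d$y))
  if (!all(is.finite(S)) || det(S) <= 0)
    stop("degenerate data: singular sample covariance", call. = FALSE)
  fit <- sem_fit_cov(.sem_models[[model_id]], S, d$n)
  structure(c(list(model_id = model_id), fit), class = "sem_fit")
}

## ML fit from a sample covariance matrix (n - 1 divisor); Wishart-likelihood
## convention so that (n - 1) * F_ML is the chi-square statistic.
sem_fit_cov <- function(model, S, n) {
  vars <- c("g", "x", "y")
  B <- matrix(0, 3, 3, dimnames = list(vars, vars))
  Psi <- rep(NA_real_, 3); names(Psi) <- vars
  Psi["g"] <- S["g", "g"]
  theta <- list(var_g = S["g", "g"])
  for (v in c("x", "y")) {
    P <- model[[v]]
    if (length(P) == 0) {
      Psi[v] <- S[v, v]
    } else {
      beta <- solve(S[P, P, drop = FALSE], S[P, v])
      B[v, P] <- beta
      Psi[v] <- S[v, v] - sum(S[v, P] * beta)
      theta[paste0(v, "_on_", P)] <- beta
    }
    theta[[paste0("psi_", v)]] <- Psi[v]
  }
  IB <- solve(diag(3) - B)
  Sigma <- IB %*% diag(Psi) %*% t(IB)
  dimnames(Sigma) <- dimnames(S)
  f_ml <- determinant(Sigma, logarithm = TRUE)$modulus -
    determinant(S, logarithm = TRUE)$modulus +
    sum(diag(S %*% solve(Sigma))) - 3
  f_ml <- as.numeric(f_ml)
  chi <- (n - 1) * f_ml
  df <- 1L
  list(theta = theta, implied = Sigma,
       chi_square = chi, df = df, bic = chi - df * log(n),
       loglik = -(n - 1) / 2 *
         (as.numeric(determinant(Sigma, TRUE)$modulus) +
            sum(diag(S %*% solve(Sigma))) + 3 * log(2 * pi)),
       n = n)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Path model (%s): chi^2(%d) = %.3f, BIC = %.3f  [n = %d]\n",
              x$model_id, x$df, x$chi_square, x$bic, x$n))
  invisible(x)
}

#' Lowest-BIC selection among the testable path models
#'
#' Fits all five testable path models and selects the one with the lowest
#' BIC.  Deterministic given the data.
#'
#' @inheritParams mr_test
#' @param tie_tol Two BICs closer than this are flagged as a tie.
#' @return An object of class `sem_selection`: `fits` (named list of
#'   [sem_fit_model()] results), `bic` (named vector), `selected`,
#'   `tie_flag`, and `failed` (models whose fit errored, normally none).
#' @examples
#' d <- simulate_triplet(scenario_spec("b"), seed = 1)
#' sem_select(d)$selected
#' @export
sem_select <- function(g, x = NULL, y = NULL, tie_tol = 1e-6) {
  d <- resolve_triplet(g, x, y)
  fits <- list(); failed <- character()
  for (m in sem_model_ids()) {
    f <- tryCatch(sem_fit_model(m, d), error = function(e) NULL)
    if (is.null(f)) failed <- c(failed, m) else fits[[m]] <- f
  }
  if (length(fits) == 0) stop("all path model fits failed", call. = FALSE)
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- names(bic)[which.min(bic)]
  srt <- sort(bic)
  tie <- length(srt) > 1 && (srt[2] - srt[1]) < tie_tol
  structure(list(fits = fits, bic = bic, selected = sel, tie_flag = tie,
                 failed = failed),
            class = "sem_selection")
}

#' @export
print.sem_selection <- function(x, ...) {
  cat("Path model selection by BIC (lower is better)\n")
  b <- sort(x$bic)
  cat(paste(sprintf("  (%s) %10.3f", names(b), b), collapse = "\n"), "\n")
  cat("  selected: (", x$selected, ")",
      if (x$tie_flag) "  [tie]", "\n", sep = "")
  if (length(x$failed)) cat("  failed fits:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
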