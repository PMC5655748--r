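#' @keywords internal
"_PACKAGE"

## Structural definition of the twelve generative scenarios.
##
## Each scenario is a pair of linear-Gaussian structural equations for the
## traits X and Y, with parents drawn from {G, X, Y, E} and one coefficient
## name per parent.  G is an additively coded SNP genotype (0/1/2); E, present
## in scenarios h-l only, is a latent N(0, sigma_e^2) environmental confounder
## that is generated but never shown to the inference methods.
.scenario_defs <- list(
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

#' Scenario identifiers
#'
#' @return Character vector of the twelve scenario letters, `"a"` to `"l"`.
#'   Scenarios `"h"`--`"l"` include the latent environmental confounder E.
#' @export
scenario_ids <- function() names(.scenario_defs)

#' Structural skeleton of a scenario
#'
#' Returns, for one generative scenario, the parent sets of the X and Y
#' equations together with the name of the coefficient attached to each
#' parent.  This is the single source of truth used both by the simulator and
#' by the benchmark truth tables (e.g. "scenarios whose Y equation contains an
#' X term" defines the set where an X to Y causal effect truly exists).
#'
#' @param scenario_id One of [scenario_ids()].
#' @return A list with elements `x` and `y` (named character vectors mapping
#'   parent variable to coefficient name) and `has_e` (logical).
#' @export
scenario_structure <- function(scenario_id) {
  def <- .scenario_defs[[match_scenario(scenario_id)]]
  list(x = def$x, y = def$y,
       has_e = any(vapply(def, function(p) "e" %in% names(p), logical(1))))
}

match_scenario <- function(scenario_id) {
  if (length(scenario_id) != 1L || !is.character(scenario_id) ||
      !scenario_id %in% names(.scenario_defs)) {
    stop("unknown scenario_id: must be one of ",
         paste(names(.scenario_defs), collapse = ", "), call. = FALSE)
  }
  scenario_id
}

#' Construct a scenario specification
#'
#' Bundles a scenario identifier with the generative parameters of the
#' simulation study.  The defaults are the study-wide values: all causal
#' effects equal to 1, trait means 10, noise standard deviations 0.3, a minor
#' allele frequency of 0.1 and 1,000 individuals per replicate.
#'
#' @param scenario_id One of [scenario_ids()].
#' @param alpha Effect of G on X (per minor allele), where present.
#' @param beta Effect of G on Y, where present.
#' @param gamma Effect along the X-Y edge in scenarios b, d, g, i and the
#'   Y-X edge in scenario c (the coefficient letter follows the generating
#'   equations, which reuse gamma for scenario c).
#' @param delta Effect of Y on X in scenarios e, f, j.
#' @param zeta Effect of the latent confounder E on each trait (scenarios
#'   h--l).
#' @param mu_x,mu_y Trait means.
#' @param sigma_x,sigma_y,sigma_e Noise standard deviations (E has mean 0 and
#'   standard deviation `sigma_e`).
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param n Sample size per replicate.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("b")
#' scenario_spec("h", zeta = 2)
#' @export
scenario_spec <- function(scenario_id,
                          alpha = 1, beta = 1, gamma = 1, delta = 1, zeta = 1,
                          mu_x = 10, mu_y = 10,
                          sigma_x = 0.3, sigma_y = 0.3, sigma_e = 0.3,
                          maf = 0.1, n = 1000L) {
  match_scenario(scenario_id)
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(delta), is.numeric(zeta),
            is.numeric(mu_x), is.numeric(mu_y))
  if (!is.numeric(sigma_x) || sigma_x <= 0 ||
      !is.numeric(sigma_y) || sigma_y <= 0 ||
      !is.numeric(sigma_e) || sigma_e <= 0)
    stop("sigma_x, sigma_y and sigma_e must be positive", call. = FALSE)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2", call. = FALSE)
  structure(
    list(scenario_id = scenario_id,
         alpha = alpha, beta = beta, gamma = gamma, delta = delta, zeta = zeta,
         mu_x = mu_x, mu_y = mu_y,
         sigma_x = sigma_x, sigma_y = sigma_y, sigma_e = sigma_e,
         maf = maf, n = n),
    class = "scenario_spec")
}

#' Default specification for a scenario
#'
#' Pure convenience wrapper: the spec with all parameters at their study
#' defaults.
#'
#' @inheritParams scenario_spec
#' @return A `scenario_spec`.
#' @export
default_spec <- function(scenario_id) scenario_spec(scenario_id)

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario (", x$scenario_id, ") specification\n", sep = "")
  str <- scenario_structure(x$scenario_id)
  eq <- function(v, parents) {
    if (length(parents) == 0)
      return(sprintf("%s ~ N(mu_%s, sigma_%s^2)", toupper(v), v, v))
    terms <- paste(sprintf("%s*%s", unlist(parents), toupper(names(parents))),
                   collapse = " + ")
    sprintf("%s ~ N(mu_%s + %s, sigma_%s^2)", toupper(v), v, terms, v)
  }
  cat("  ", eq("x", str$x), "\n  ", eq("y", str$y), "\n", sep = "")
  if (str$has_e) cat("   E ~ N(0, sigma_e^2)   [latent]\n")
  pars <- unlist(x[c("alpha", "beta", "gamma", "delta", "zeta",
                     "mu_x", "mu_y", "sigma_x", "sigma_y", "sigma_e", "maf")])
  cat("  ", paste(names(pars), pars, sep = "=", collapse = ", "),
      ", n=", x$n, "\n", sep = "")
  invisible(x)
}
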