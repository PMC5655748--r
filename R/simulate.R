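## Replicate simulation under the twelve generative scenarios.

#' Derive a reproducible substream seed
#'
#' Deterministically folds a base seed, a scenario letter and a replicate
#' index into a single integer seed, so that replicate r of scenario s can be
#' regenerated in isolation (and, in principle, in parallel) without running
#' through the preceding replicates' random numbers.
#'
#' @param base_seed Integer base seed for a whole experiment.
#' @param scenario_id One of [scenario_ids()] (or any short string label).
#' @param replicate Replicate index (1-based).
#' @return A single integer in \[0, 2^31 - 2\], suitable for [set.seed()].
#' @export
triplet_seed <- function(base_seed, scenario_id, replicate = 1L) {
  stopifnot(length(base_seed) == 1L, is.finite(base_seed),
            length(replicate) == 1L, is.finite(replicate))
  ## multiplicative-fold hash kept inside double precision:
  ## 2^31 * 69069 < 2^53, so no intermediate overflow
  m <- 2147483647
  h <- abs(as.numeric(base_seed)) %% m
  for (v in c(utf8ToInt(paste(scenario_id, collapse = "")),
              as.numeric(replicate), 104729)) {
    h <- (h * 69069 + v) %% m
  }
  as.integer(h)
}

## Evaluate thunk with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws independent genotypes coded as the number of minor alleles (0, 1, 2)
#' with frequencies \eqn{(1-q)^2, 2q(1-q), q^2} for minor allele frequency
#' \eqn{q}.
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param seed Optional integer seed (local to this call).
#' @return Integer vector of length `n` with values in \{0, 1, 2\}.
#' @examples
#' table(simulate_genotypes(1000, 0.1, seed = 1))
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  with_seed(seed, {
    ## sum of two independent allele draws = binomial(2, maf)
    as.integer(stats::rbinom(n, 2L, maf))
  })
}

#' Simulate one (G, X, Y) replicate
#'
#' Generates genotypes under Hardy-Weinberg equilibrium and then the traits X
#' and Y from the scenario's linear-Gaussian structural equations, in the
#' topological order the equations imply (the latent confounder E, when the
#' scenario includes one, is drawn first).  All noise terms are independent
#' given parents.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional integer seed; see [triplet_seed()] for deriving
#'   per-replicate substream seeds.
#' @return An object of class `triplet_data`: a list with integer vector `g`,
#'   numeric vectors `x`, `y`, the latent `e` (scenarios h--l only), the truth
#'   label `truth` and the seed used (`seed_record`, possibly `NA`).  The
#'   latent confounder is retained for diagnostics but deliberately dropped by
#'   [as.data.frame.triplet_data()] and by the file writer, since it is
#'   unmeasured by construction.
#' @examples
#' d <- simulate_triplet(scenario_spec("b", n = 500), seed = 1)
#' cor(d$x, d$y)
#' @export
simulate_triplet <- function(spec, seed = NULL) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  def <- scenario_structure(spec$scenario_id)
  with_seed(seed, {
    n <- spec$n
    vars <- list(g = as.numeric(simulate_genotypes(n, spec$maf)))
    if (def$has_e) vars$e <- stats::rnorm(n, 0, spec$sigma_e)
    ## topological order of the two trait equations
    order_xy <- if ("y" %in% names(def$x)) c("y", "x") else c("x", "y")
    for (v in order_xy) {
      parents <- def[[v]]
      mu <- if (v == "x") spec$mu_x else spec$mu_y
      sd <- if (v == "x") spec$sigma_x else spec$sigma_y
      lin <- rep(mu, n)
      for (p in names(parents)) lin <- lin + spec[[parents[[p]]]] * vars[[p]]
      vars[[v]] <- stats::rnorm(n, lin, sd)
    }
    structure(
      list(g = as.integer(vars$g), x = vars$x, y = vars$y,
           e = if (def$has_e) vars$e else NULL,
           truth = spec$scenario_id, spec = spec,
           seed_record = if (is.null(seed)) NA_integer_ else as.integer(seed)),
      class = "triplet_data")
  })
}

#' @export
print.triplet_data <- function(x, ...) {
  cat("triplet_data: n =", length(x$g), " truth = (", x$truth, ")",
      if (!is.null(x$e)) " [latent E generated]", "\n")
  cat("  genotype counts:",
      paste(0:2, tabulate(x$g + 1L, 3L), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Method-facing view of a replicate
#'
#' @param x A `triplet_data`.
#' @param row.names,optional,... Passed on conventionally (unused).
#' @return A data frame with columns `g`, `x`, `y` only; the latent
#'   environmental confounder, when present, is not exposed.
#' @export
as.data.frame.triplet_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(g = x$g, x = x$x, y = x$y)
}

#' Write / read one replicate as delimited text
#'
#' The data file holds the observed columns `g`, `x`, `y` (tab separated,
#' header line; the latent confounder is never written).  A JSON sidecar
#' records the generating `scenario_spec` and seed so the replicate can be
#' regenerated.
#'
#' @param data A `triplet_data` (or data frame with columns `g`, `x`, `y`).
#' @param file Path of the data file.
#' @param sidecar Path of the JSON sidecar; default `<file>.json`; `NULL`
#'   suppresses it (and is the only option for plain data frames).
#' @return `file`, invisibly.
#' @export
write_triplet <- function(data, file, sidecar = paste0(file, ".json")) {
  df <- as.data.frame(data)
  stopifnot(all(c("g", "x", "y") %in% names(df)))
  utils::write.table(df[, c("g", "x", "y")], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar) && inherits(data, "triplet_data")) {
    rec <- c(unclass(data$spec),
             list(seed_record = data$seed_record, truth = data$truth))
    jsonlite::write_json(rec, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' @rdname write_triplet
#' @param truth Optional truth label to attach when reading user data.
#' @export
read_triplet <- function(file, truth = NA_character_) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  stopifnot(all(c("g", "x", "y") %in% names(df)))
  g <- as.integer(df$g)
  if (!all(g %in% 0:2)) stop("column g must contain genotypes coded 0/1/2")
  structure(list(g = g, x = as.numeric(df$x), y = as.numeric(df$y),
                 e = NULL, truth = truth, spec = NULL,
                 seed_record = NA_integer_),
            class = "triplet_data")
}

## Resolve (g, x, y) arguments: methods accept either three vectors or a
## single triplet_data / data frame in the first position.
resolve_triplet <- function(g, x = NULL, y = NULL) {
  if (is.list(g) && is.null(x) && is.null(y)) {
    d <- g
    g <- d$g; x <- d$x; y <- d$y
  }
  g <- as.numeric(g); x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(g) || length(y) != length(g))
    stop("g, x and y must have equal length", call. = FALSE)
  if (anyNA(g) || anyNA(x) || anyNA(y))
    stop("missing values are not supported", call. = FALSE)
  list(g = g, x = x, y = y, n = length(g))
}
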