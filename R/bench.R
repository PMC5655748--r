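## Replicated benchmark: simulate scenarios, apply methods, aggregate
## detection proportions, proportion-correct and mean-score matrices.

#' Truth tables for the benchmark
#'
#' Derived programmatically from the scenario structures rather than
#' hand-coded: the correct model for a scenario is its structure with the
#' latent confounder dropped, matched against the admissible DAGs; the MR
#' truth set is the set of scenarios whose Y equation contains an X term
#' (a true X to Y causal effect); the CIT truth set is the set of scenarios
#' whose confounder-free structure is exactly G to X to Y.
#'
#' @return A list with `correct_model` (named by scenario: one of the DAG ids
#'   or `NA`), `mr_true_scenarios`, `cit_true_scenarios`, `sem_correct`,
#'   `buf_correct` (partition codes), `bn_correct`.
#' @export
truth_tables <- function() {
  dags <- enumerate_dags()
  sig <- function(xp, yp) paste(paste(sort(xp), collapse = "+"), "|",
                                paste(sort(yp), collapse = "+"))
  dag_sig <- vapply(dags, function(d) sig(d$parents$x, d$parents$y), "")
  correct <- vapply(scenario_ids(), function(s) {
    st <- scenario_structure(s)
    xp <- setdiff(names(st$x), "e")
    yp <- setdiff(names(st$y), "e")
    id <- names(dag_sig)[dag_sig == sig(xp, yp)]
    if (length(id) == 1) id else NA_character_
  }, "")
  mr_true <- names(Filter(function(s) "x" %in% names(scenario_structure(s)$y),
                          stats::setNames(as.list(scenario_ids()), scenario_ids())))
  cit_true <- names(correct)[!is.na(correct) & correct == "b"]
  part <- buf_partitions()
  alias_to_part <- stats::setNames(part$partition, part$alias)
  list(
    correct_model = correct,
    mr_true_scenarios = mr_true,
    cit_true_scenarios = cit_true,
    sem_correct = stats::setNames(
      ifelse(correct %in% sem_model_ids(), correct, NA_character_),
      names(correct)),
    buf_correct = stats::setNames(
      unname(alias_to_part[ifelse(is.na(correct), "zz", correct)]),
      names(correct)),
    bn_correct = correct
  )
}

.bench_methods <- c("mr", "cit", "sem", "buf", "bnlearn", "deal")

#' Run one scenario of the replicated benchmark
#'
#' Simulates `n_reps` independent replicates of a scenario and applies each
#' requested method, aggregating detection proportions (MR, CIT) or selection
#' outcomes and mean score tables (SEM, BUF and the two network scores).
#' Replicate r uses the substream seed `triplet_seed(base_seed, scenario, r)`,
#' so the whole run is deterministic given `base_seed` and any subset of
#' replicates can be regenerated independently.  Method failures (degenerate
#' replicates) are counted, never propagated.
#'
#' @param scenario_id One of [scenario_ids()].
#' @param methods Subset of `c("mr","cit","sem","buf","bnlearn","deal")`.
#' @param n_reps Number of replicate data sets.
#' @param base_seed Integer base seed.
#' @param spec_args Named list of [scenario_spec()] overrides (e.g.
#'   `list(zeta = 2, n = 500)`).
#' @param threshold Detection p-value threshold for MR and the CIT.
#' @param b_perm,coding Passed to [cit_test()].
#' @param sigma_a_grid Passed to [buf_bf()].
#' @param iss Passed to the `deal` network score.
#' @return An object of class `bench_summary`; see [as.data.frame.bench_summary()]
#'   for a tidy view.  Per selection method the outcome proportions
#'   `correct`, `incorrect`, `tie`, `failure` sum to one (a tie whose tied set
#'   contains the correct model counts as correct).
#' @examples
#' run_scenario("b", methods = c("mr", "sem"), n_reps = 20, base_seed = 1)
#' @export
run_scenario <- function(scenario_id, methods = .bench_methods,
                         n_reps = 1000L, base_seed = 1L,
                         spec_args = list(), threshold = 0.05,
                         b_perm = 1000L, coding = "additive",
                         sigma_a_grid = 0.1, iss = 6) {
  methods <- match.arg(methods, .bench_methods, several.ok = TRUE)
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L, length(methods) >= 1L)
  spec <- do.call(scenario_spec, c(list(scenario_id = scenario_id), spec_args))
  truth <- truth_tables()

  acc <- lapply(stats::setNames(methods, methods), function(m) list())
  for (r in seq_len(n_reps)) {
    rs <- triplet_seed(base_seed, scenario_id, r)
    d <- simulate_triplet(spec, seed = rs)
    for (m in methods) {
      res <- tryCatch(switch(
        m,
        mr = mr_test(d, threshold = threshold),
        cit = cit_test(d, b_perm = b_perm, threshold = threshold,
                       coding = coding, seed = triplet_seed(rs, "cit", 1L)),
        sem = sem_select(d),
        buf = buf_bf(d, sigma_a_grid = sigma_a_grid),
        bnlearn = bn_score(d, score = "bic_cg"),
        deal = bn_score(d, score = "deal", iss = iss)
      ), error = function(e) e)
      acc[[m]][[r]] <- res
    }
  }

  summaries <- lapply(stats::setNames(methods, methods), function(m)
    bench_aggregate(m, acc[[m]], scenario_id, truth))
  structure(list(scenario = scenario_id, n_reps = n_reps, n = spec$n,
                 base_seed = base_seed, spec = spec, threshold = threshold,
                 methods = summaries),
            class = "bench_summary")
}

bench_aggregate <- function(method, results, scenario, truth) {
  failed <- vapply(results, inherits, logical(1), "error")
  n_reps <- length(results)
  ok <- results[!failed]

  if (method %in% c("mr", "cit")) {
    det <- vapply(ok, `[[`, logical(1), "detected")
    flag <- vapply(ok, `[[`, character(1), "flag") != "ok"
    truth_set <- if (method == "mr") truth$mr_true_scenarios
                 else truth$cit_true_scenarios
    return(list(kind = "detection", n_reps = n_reps,
                detection_rate = sum(det) / n_reps,
                true_relationship = scenario %in% truth_set,
                failure_rate = (sum(failed) + sum(flag)) / n_reps))
  }

  correct <- switch(method, sem = truth$sem_correct[[scenario]],
                    buf = truth$buf_correct[[scenario]],
                    truth$bn_correct[[scenario]])
  cat_of <- function(res) {
    if (method == "sem") {
      sel <- res$selected; tie <- res$tie_flag
      tied_set <- if (tie) {
        b <- sort(res$bic); names(b)[b - b[1] < 1e-6]
      } else sel
    } else if (method == "buf") {
      sel <- res$selected; tie <- res$tie_flag
      tied_set <- if (tie) {
        b <- sort(res$log10_bf, decreasing = TRUE)
        names(b)[b[1] - b < 1e-9]
      } else sel
    } else {
      if (res$flag != "ok")
        return(list(cat = "failure", sel = NA_character_))
      sel <- res$selected; tie <- res$tie_flag
      tied_set <- sel  # equivalence class; unrelated ties flagged separately
    }
    cat <- if (is.na(correct)) NA_character_
      else if (tie && correct %in% tied_set) "correct"
      else if (tie) "tie"
      else if (correct %in% sel) "correct"
      else "incorrect"
    list(cat = cat, sel = paste(sel, collapse = "/"))
  }
  cats <- lapply(ok, cat_of)
  sel_freq <- table(vapply(cats, `[[`, character(1), "sel"))
  catv <- vapply(cats, `[[`, character(1), "cat")
  is_fail <- failed
  is_fail[!failed] <- !is.na(catv) & catv == "failure"
  nfail <- sum(is_fail)
  catv <- catv[!is.na(catv) & catv != "failure"]

  score_of <- function(res) switch(method, sem = res$bic,
                                   buf = res$log10_bf, res$scores)
  finite_ok <- Filter(function(r) all(is.finite(score_of(r))), ok)
  mean_score <- if (length(finite_ok))
    rowMeans(vapply(finite_ok, score_of, score_of(finite_ok[[1]])))
  else NULL

  list(kind = "selection", n_reps = n_reps,
       correct_model = correct,
       correct_rate = if (is.na(correct)) NA_real_ else sum(catv == "correct") / n_reps,
       incorrect_rate = if (is.na(correct)) NA_real_ else sum(catv == "incorrect") / n_reps,
       tie_rate = if (is.na(correct)) NA_real_ else sum(catv == "tie") / n_reps,
       failure_rate = nfail / n_reps,
       mean_score = mean_score,
       selected_freq = sel_freq / max(1, sum(sel_freq)))
}

#' @export
print.bench_summary <- function(x, ...) {
  cat(sprintf("Benchmark, scenario (%s): %d replicates of n = %d (seed %d)\n",
              x$scenario, x$n_reps, x$n, x$base_seed))
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    if (s$kind == "detection") {
      cat(sprintf("  %-8s detection %.3f (%s detection; failures %.3f)\n",
                  m, s$detection_rate,
                  ifelse(s$true_relationship, "true", "false"), s$failure_rate))
    } else {
      top <- names(sort(unclass(s$selected_freq), decreasing = TRUE))[1]
      cat(sprintf("  %-8s correct %s (correct model %s; modal choice %s; ties %s, failures %.3f)\n",
                  m,
                  ifelse(is.na(s$correct_rate), "n/a",
                         sprintf("%.3f", s$correct_rate)),
                  ifelse(is.na(s$correct_model), "none", s$correct_model),
                  top,
                  ifelse(is.na(s$tie_rate), "n/a", sprintf("%.3f", s$tie_rate)),
                  s$failure_rate))
    }
  }
  invisible(x)
}

#' Tidy view of a benchmark summary
#'
#' @param x A `bench_summary`.
#' @param row.names,optional,... Conventional (unused).
#' @return One row per scenario x method x statistic.
#' @export
as.data.frame.bench_summary <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    stats_ <- if (s$kind == "detection")
      c(detection_rate = s$detection_rate, failure_rate = s$failure_rate)
    else c(correct_rate = s$correct_rate, incorrect_rate = s$incorrect_rate,
           tie_rate = s$tie_rate, failure_rate = s$failure_rate)
    rows[[m]] <- data.frame(scenario = x$scenario, method = m,
                            statistic = names(stats_), value = unname(stats_),
                            n_reps = s$n_reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect-size sweep
#'
#' Re-runs [run_scenario()] over a grid of values of one generative
#' parameter, all other parameters held at their defaults (or at
#' `spec_args`).
#'
#' @param parameter One of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`,
#'   `"zeta"` (or any [scenario_spec()] numeric parameter).
#' @param values Numeric vector of parameter values.
#' @inheritParams run_scenario
#' @param ... Further arguments passed to [run_scenario()].
#' @return An object of class `bench_sweep`: list of `bench_summary`, one per
#'   value, with the swept value attached.
#' @export
run_sweep <- function(parameter, values, scenario_id,
                      methods = .bench_methods, n_reps = 200L,
                      base_seed = 1L, spec_args = list(), ...) {
  stopifnot(is.character(parameter), length(parameter) == 1L,
            length(values) >= 1L)
  out <- lapply(seq_along(values), function(i) {
    sa <- spec_args; sa[[parameter]] <- values[i]
    s <- run_scenario(scenario_id, methods = methods, n_reps = n_reps,
                      base_seed = triplet_seed(base_seed, parameter, i),
                      spec_args = sa, ...)
    s$swept <- list(parameter = parameter, value = values[i])
    s
  })
  structure(list(parameter = parameter, values = values, summaries = out),
            class = "bench_sweep")
}

#' @export
print.bench_sweep <- function(x, ...) {
  cat("Sweep over", x$parameter, "=",
      paste(x$values, collapse = ", "), "\n")
  for (s in x$summaries) {
    cat(sprintf("-- %s = %g --\n", x$parameter, s$swept$value))
    print(s)
  }
  invisible(x)
}

#' Mean-score matrix across scenarios
#'
#' Assembles, for each selection method present, the matrix of mean scores
#' with one row per tested model and one column per simulated scenario, the
#' per-column preferred (best mean score) model and the correct model.
#'
#' @param summaries A list of `bench_summary` objects (or a `bench_sweep`).
#' @param out_csv,out_json Optional output paths; the CSV holds one block of
#'   rows per method, the JSON mirrors the full structure.
#' @return Named list (per method) of lists with `mean_score` matrix,
#'   `preferred` and `correct` (per scenario).  Empty input yields an empty
#'   artifact.
#' @export
summarize_table2 <- function(summaries, out_csv = NULL, out_json = NULL) {
  if (inherits(summaries, "bench_summary")) summaries <- list(summaries)
  if (inherits(summaries, "bench_sweep")) summaries <- summaries$summaries
  sel_methods <- c("sem", "buf", "bnlearn", "deal")
  out <- list()
  for (m in sel_methods) {
    have <- Filter(function(s) m %in% names(s$methods) &&
                     !is.null(s$methods[[m]]$mean_score), summaries)
    if (!length(have)) next
    cols <- lapply(have, function(s) s$methods[[m]]$mean_score)
    models <- names(cols[[1]])
    mat <- vapply(cols, function(v) v[models], numeric(length(models)))
    mat <- matrix(mat, nrow = length(models),
                  dimnames = list(models,
                                  vapply(have, `[[`, "", "scenario")))
    better <- if (m == "sem") which.min else which.max
    preferred <- apply(mat, 2, function(v) models[better(v)])
    correct <- vapply(have, function(s)
      s$methods[[m]]$correct_model %||% NA_character_, "")
    names(correct) <- colnames(mat)
    out[[m]] <- list(mean_score = mat, preferred = preferred,
                     correct = correct)
  }
  if (!is.null(out_csv)) {
    rows <- if (length(out)) {
      do.call(rbind, c(lapply(names(out), function(m) {
        mat <- out[[m]]$mean_score
        data.frame(method = m, tested_model = rownames(mat),
                   as.data.frame(mat, check.names = FALSE))
      }), list(make.row.names = FALSE)))
    } else data.frame(method = character(), tested_model = character())
    utils::write.csv(rows, out_csv, row.names = FALSE)
  }
  if (!is.null(out_json))
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
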