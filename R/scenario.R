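#' Detect cognitive conflicts on the causal network
#'
#' A cognitive conflict is an implication whose sign means a desired change
#' and a contented construct collide. Two directed kinds are flagged over
#' every nonzero edge `w[i, j]`:
#'
#' * `goal_harms_content`: the source i is discrepant (change desired with
#'   direction `g_i`), the target j is congruent, and pursuing the goal
#'   pushes j away from its ideal pole:
#'   `sign(w[i, j] * g_i) == -sign(I_j)`.
#' * `content_blocks_goal`: the source i is congruent (held at its current
#'   activation `a0_i`), the target j is discrepant, and the held position
#'   pushes j against its desired direction:
#'   `sign(w[i, j] * a0_i) == -sign(g_j)`.
#'
#' Severity is `|w|`; the result is sorted by severity descending, ties
#' broken by (source, target) index order.
#'
#' @param model an [fcm_model()].
#' @param statuses a `construct_status` data frame aligned with the model
#'   (from [classify_grid()] or [classify_construct()]).
#' @return A data frame of class `conflict_report` with columns `source`,
#'   `target`, `weight`, `kind`, `severity` (possibly zero rows).
#' @export
detect_conflicts <- function(model, statuses) {
  stopifnot(inherits(model, "fcm_model"))
  n <- length(model$a0)
  if (nrow(statuses) != n)
    stop("statuses and model are not aligned", call. = FALSE)
  W <- model$W
  a0 <- model$a0
  g <- statuses$desired_direction
  I <- statuses$ideal_activation
  st <- statuses$status
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- W[i, j]
    if (i == j || w == 0) next
    kind <- NULL
    if (st[i] == "discrepant" && st[j] == "congruent" &&
        sign(w * g[i]) == -sign(I[j]) && sign(I[j]) != 0) {
      kind <- "goal_harms_content"
    } else if (st[i] == "congruent" && st[j] == "discrepant" &&
               sign(w * a0[i]) == -sign(g[j]) && sign(g[j]) != 0) {
      kind <- "content_blocks_goal"
    }
    if (!is.null(kind))
      rows[[length(rows) + 1L]] <-
        data.frame(source = i, target = j, weight = w, kind = kind,
                   severity = abs(w), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = integer(), target = integer(), weight = numeric(),
               kind = character(), severity = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$severity, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("conflict_report", "data.frame"))
}

#' Specify a what-if intervention scenario
#'
#' Three intervention mechanisms, combinable:
#' * `perturbations`: one-shot overrides of the initial activation (a
#'   behaviour change imposed at t = 0 and then left to the dynamics);
#' * `clamps`: activations held fixed at every iteration (a permanently
#'   sustained intervention);
#' * `weight_edits`: changes to the implication structure itself, given as
#'   *stored* scores in -3..3 (0 removes the edge), re-encoded through the
#'   same elicitation-frame rule as [build_weight_matrix()].
#'
#' @param perturbations named numeric vector/list, construct index ->
#'   initial activation in [-1, 1].
#' @param clamps named numeric vector/list, construct index -> fixed
#'   activation in [-1, 1].
#' @param weight_edits data frame with columns `source`, `target`, `score`
#'   (integers; `score` in -3..3, 0 = remove edge).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(perturbations = NULL, clamps = NULL,
                          weight_edits = NULL) {
  if (!is.null(weight_edits)) {
    weight_edits <- as.data.frame(weight_edits)
    stopifnot(all(c("source", "target", "score") %in% names(weight_edits)))
    if (any(weight_edits$score < -3 | weight_edits$score > 3 |
            weight_edits$score != round(weight_edits$score)))
      stop("edited scores must be integers in -3..3", call. = FALSE)
    if (any(weight_edits$source == weight_edits$target))
      stop("weight edits may not address the diagonal", call. = FALSE)
  }
  structure(list(perturbations = perturbations, clamps = clamps,
                 weight_edits = weight_edits),
            class = "scenario_spec")
}

#' Read / write a scenario specification as JSON
#'
#' @param spec a [scenario_spec()].
#' @param path file path.
#' @return `write_scenario_json()` returns `path` invisibly;
#'   `read_scenario_json()` returns a `scenario_spec`.
#' @export
write_scenario_json <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  jsonlite::write_json(
    list(perturbations = as.list(spec$perturbations),
         clamps = as.list(spec$clamps),
         weight_edits = spec$weight_edits),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_or <- function(x) if (!length(x)) NULL else unlist(x)
  scenario_spec(perturbations = empty_or(obj$perturbations),
                clamps = empty_or(obj$clamps),
                weight_edits = if (length(obj$weight_edits))
                  obj$weight_edits else NULL)
}

#' Apply a scenario to a model
#'
#' Returns a *new* model: perturbation entries replace the corresponding
#' initial activations; weight edits are re-encoded into canonical weights
#' through the elicitation-frame rule of [build_weight_matrix()] (using the
#' original grid's Self-Now / Ideal-Self, not the perturbed state); clamps
#' are attached for [fcm_simulate()]. The input model is never mutated.
#'
#' @param model an [fcm_model()].
#' @param grid,imp the case the model was built from (needed to re-encode
#'   edited scores in the elicitation frame).
#' @param spec a [scenario_spec()].
#' @return A new `fcm_model`.
#' @export
apply_scenario <- function(model, grid, imp, spec) {
  stopifnot(inherits(model, "fcm_model"), inherits(spec, "scenario_spec"))
  n <- length(model$a0)
  a0 <- model$a0
  if (!is.null(spec$perturbations)) {
    p <- normalize_clamps(spec$perturbations, n)  # same shape/range checks
    a0[as.integer(names(p))] <- unname(p)
  }
  W <- model$W
  if (!is.null(spec$weight_edits) && nrow(spec$weight_edits)) {
    stopifnot(inherits(grid, "repgrid"), inherits(imp, "impgrid"))
    ed <- spec$weight_edits
    if (any(ed$source < 1 | ed$source > n | ed$target < 1 | ed$target > n))
      stop("weight edit index out of range", call. = FALSE)
    a0_orig <- build_activation_vector(grid)
    ideal <- ideal_vector(grid)
    d <- -sign(a0_orig)
    mid <- d == 0
    d[mid] <- sign(ideal[mid] - a0_orig[mid])
    for (k in seq_len(nrow(ed))) {
      i <- ed$source[k]; j <- ed$target[k]; s <- ed$score[k]
      if (s != 0 && d[i] == 0)
        stop(sprintf(
          "cannot encode an edit from construct %d: no defined change direction",
          i), call. = FALSE)
      W[i, j] <- if (s == 0) 0 else d[i] * s / 3
    }
  }
  clamps <- model$clamps
  if (!is.null(spec$clamps)) {
    cl <- normalize_clamps(spec$clamps, n)
    clamps <- c(clamps[setdiff(names(clamps), names(cl))], cl)
  }
  fcm_model(a0, W, model$config,
            clamps = if (length(clamps)) clamps else NULL)
}

#' Compare a scenario run against a baseline run
#'
#' For each construct: initial and final distances to the ideal under both
#' runs, achieved flags, and a *relapse* indicator — the scenario brings the
#' construct within the achievement tolerance at the first iteration
#' (distance at t = 1 below `tau`) but the system drifts back out by the
#' end (final distance above `tau`). Aggregates report the mean final
#' distance of each run.
#'
#' @param baseline,scenario lists with components `trace` (an `fcm_trace`)
#'   and `dynamics` (an `fcm_dynamics`), as produced by [fcm_simulate()]
#'   and [distance_trajectory()] on the same construct set.
#' @return A list of class `scenario_comparison` with a per-construct data
#'   frame `constructs` and an `aggregate` list.
#' @export
compare_scenarios <- function(baseline, scenario) {
  btr <- baseline$trace; bdy <- baseline$dynamics
  str_ <- scenario$trace; sdy <- scenario$dynamics
  stopifnot(inherits(btr, "fcm_trace"), inherits(bdy, "fcm_dynamics"),
            inherits(str_, "fcm_trace"), inherits(sdy, "fcm_dynamics"))
  n <- ncol(btr$states)
  if (ncol(str_$states) != n)
    stop("baseline and scenario construct sets differ", call. = FALSE)
  tau <- sdy$tau
  b_d <- bdy$distances; s_d <- sdy$distances
  s_t1 <- s_d[min(2L, nrow(s_d)), ]
  per <- data.frame(
    construct = seq_len(n),
    baseline_initial = b_d[1L, ],
    baseline_final = b_d[nrow(b_d), ],
    baseline_achieved = bdy$achieved,
    scenario_initial = s_d[1L, ],
    scenario_final = s_d[nrow(s_d), ],
    scenario_achieved = sdy$achieved,
    relapse = (s_t1 < tau) & (s_d[nrow(s_d), ] > tau)
  )
  structure(list(
    constructs = per,
    aggregate = list(
      baseline_mean_final = mean(b_d[nrow(b_d), ]),
      scenario_mean_final = mean(s_d[nrow(s_d), ]),
      tau = tau)
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (distances to Ideal-Self)\n")
  df <- x$constructs
  cat(sprintf("  mean final distance: baseline %.3f, scenario %.3f\n",
              x$aggregate$baseline_mean_final,
              x$aggregate$scenario_mean_final))
  cat(sprintf("  achieved: baseline %d, scenario %d of %d; relapses: %d\n",
              sum(df$baseline_achieved), sum(df$scenario_achieved),
              nrow(df), sum(df$relapse)))
  print(format(df, digits = 3L), ...)
  invisible(x)
}

#' Serialize a scenario comparison
#'
#' @param cmp a `scenario_comparison`.
#' @param path output file.
#' @param format `"json"` or `"txt"` (human-readable table).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path, format = c("json", "txt")) {
  format <- match.arg(format)
  stopifnot(inherits(cmp, "scenario_comparison"))
  if (format == "json") {
    jsonlite::write_json(list(constructs = cmp$constructs,
                              aggregate = cmp$aggregate),
                         path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(cmp)
  }
  invisible(path)
}
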