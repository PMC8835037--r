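#' Simulation configuration for the FCM engine
#'
#' Controls the update rule, the squashing (threshold) function and the
#' convergence machinery of [fcm_simulate()].
#'
#' @param rule update rule. `"self_memory"` (default) adds the node's own
#'   previous activation to its weighted inputs before squashing, so a node
#'   with no incoming edges keeps (a squashed version of) its state;
#'   `"kosko"` is the classical rule using weighted inputs only.
#' @param threshold squashing function keeping activations in [-1, 1]:
#'   `"tanh"` (default), `"clamp"` (hard saturation) or `"sign"` (tri-valued
#'   -1/0/+1).
#' @param lambda positive slope of the tanh threshold (ignored otherwise).
#' @param max_iterations iteration budget.
#' @param fixed_point_tolerance fixed point declared when the max-abs
#'   difference between consecutive states drops below this.
#' @param cycle_detection_horizon how many past states are scanned for a
#'   repeat (limit-cycle detection); states are compared after rounding.
#' @param state_rounding_digits rounding used only for cycle detection.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rule = c("self_memory", "kosko"),
                       threshold = c("tanh", "clamp", "sign"),
                       lambda = 1,
                       max_iterations = 100L,
                       fixed_point_tolerance = 1e-4,
                       cycle_detection_horizon = 50L,
                       state_rounding_digits = 6L) {
  rule <- match.arg(rule)
  threshold <- match.arg(threshold)
  stopifnot(lambda > 0, max_iterations >= 1, fixed_point_tolerance > 0,
            cycle_detection_horizon >= 1, state_rounding_digits >= 1)
  structure(list(rule = rule, threshold = threshold, lambda = lambda,
                 max_iterations = as.integer(max_iterations),
                 fixed_point_tolerance = fixed_point_tolerance,
                 cycle_detection_horizon = as.integer(cycle_detection_horizon),
                 state_rounding_digits = as.integer(state_rounding_digits)),
            class = "sim_config")
}

#' Apply the configured threshold (squashing) function
#'
#' @param x finite numeric vector.
#' @param config a [sim_config()].
#' @return values in [-1, 1]: `tanh(lambda * x)`, `min(1, max(-1, x))`, or
#'   `sign(x)` according to `config$threshold`.
#' @export
fcm_threshold <- function(x, config = sim_config()) {
  if (any(!is.finite(x))) stop("non-finite activation input", call. = FALSE)
  switch(config$threshold,
         tanh = tanh(config$lambda * x),
         clamp = pmin(1, pmax(-1, x)),
         sign = sign(x))
}

#' Build the initial activation vector from the Self-Now ratings
#'
#' @param grid a [repgrid()] with a `self_now` element.
#' @return numeric vector, one canonical-frame activation per construct.
#' @export
build_activation_vector <- function(grid) {
  stopifnot(inherits(grid, "repgrid"))
  rating_to_activation(grid$ratings[, role_index(grid, "self_now")])
}

#' Build the FCM weight matrix from an implications grid
#'
#' The implications grid is elicited in the frame "if you moved from your
#' current pole to the opposite pole, which constructs would change, and
#' toward which pole?". Its stored score `s[i, j]` is expressed in the
#' right-pole-positive frame of the *target* j (sign = implied pole,
#' magnitude = intensity 1..3). The hypothesized movement direction of the
#' *source* i is therefore `d_i = -sign(a0_i)` (away from the current pole),
#' falling back to the desired direction (toward the ideal) when the
#' Self-Now sits at the midpoint. The canonical causal coefficient is
#'
#'   `w[i, j] = d_i * s[i, j] / 3`
#'
#' so that a unit movement of i in direction `d_i` pushes each target j in
#' direction `sign(s[i, j])` with strength `|s[i, j]| / 3`.
#'
#' @param imp an [impgrid()] aligned with `grid`.
#' @param grid the companion [repgrid()].
#' @return n x n numeric weight matrix with zero diagonal, entries in
#'   [-1, 1].
#' @export
build_weight_matrix <- function(imp, grid) {
  stopifnot(inherits(imp, "impgrid"), inherits(grid, "repgrid"))
  bad <- check_impgrid(imp, grid)
  if (length(bad))
    stop(paste(bad, collapse = "; "), call. = FALSE)
  a0 <- build_activation_vector(grid)
  ideal <- rating_to_activation(grid$ratings[, role_index(grid, "ideal_self")])
  d <- -sign(a0)
  mid <- d == 0
  d[mid] <- sign(ideal[mid] - a0[mid])
  n <- length(a0)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (all(imp$scores[i, ] == 0L)) next
    if (d[i] == 0)
      stop(sprintf(
        "construct %d has implications but no defined change direction (Self-Now and Ideal-Self both at the midpoint)",
        i), call. = FALSE)
    W[i, ] <- d[i] * imp$scores[i, ] / 3
  }
  diag(W) <- 0
  W
}

#' Assemble an FCM model
#'
#' @param a0 initial activation vector (entries in [-1, 1]).
#' @param W n x n weight matrix, `W[i, j]` = causal coefficient from
#'   construct i to construct j, entries in [-1, 1], zero diagonal.
#' @param config a [sim_config()].
#' @param clamps optional named numeric vector or list mapping construct
#'   index to a fixed activation, applied at every step of
#'   [fcm_simulate()].
#' @return A list of class `fcm_model`.
#' @export
fcm_model <- function(a0, W, config = sim_config(), clamps = NULL) {
  a0 <- as.numeric(a0)
  W <- as.matrix(W)
  n <- length(a0)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (any(abs(a0) > 1 + 1e-12))
    stop("initial activations must lie in [-1, 1]", call. = FALSE)
  if (any(abs(W) > 1 + 1e-12))
    stop("weights must lie in [-1, 1]", call. = FALSE)
  if (any(diag(W) != 0))
    stop("weight matrix must have a zero diagonal", call. = FALSE)
  clamps <- normalize_clamps(clamps, n)
  structure(list(a0 = a0, W = W, config = config, clamps = clamps),
            class = "fcm_model")
}

normalize_clamps <- function(clamps, n) {
  if (is.null(clamps) || !length(clamps)) return(numeric(0))
  v <- unlist(clamps)
  idx <- as.integer(names(v))
  if (anyNA(idx))
    stop("clamps must be named by construct index", call. = FALSE)
  if (any(idx < 1L | idx > n))
    stop("clamp index out of range", call. = FALSE)
  if (any(abs(v) > 1))
    stop("clamp values must lie in [-1, 1]", call. = FALSE)
  setNames(as.numeric(v), idx)
}

#' Build an FCM model straight from a case
#'
#' Convenience wrapper: [build_activation_vector()] +
#' [build_weight_matrix()] + [fcm_model()].
#'
#' @inheritParams build_weight_matrix
#' @inheritParams fcm_model
#' @return An `fcm_model`.
#' @export
build_fcm <- function(grid, imp, config = sim_config()) {
  fcm_model(build_activation_vector(grid), build_weight_matrix(imp, grid),
            config)
}

#' One synchronous propagation step
#'
#' Under the `kosko` rule each node's new activation is the squashed sum of
#' its weighted inputs, `a'_j = f(sum_i w_ij a_i)`; under `self_memory` the
#' node's own previous activation joins the sum,
#' `a'_j = f(a_j + sum_i w_ij a_i)`. The diagonal of W is zero, so a node
#' never feeds itself through an edge.
#'
#' @param a activation vector, entries in [-1, 1].
#' @param W weight matrix (source in rows, target in columns).
#' @param config a [sim_config()].
#' @return the next activation vector.
#' @export
propagate_step <- function(a, W, config = sim_config()) {
  a <- as.numeric(a)
  if (length(a) != nrow(W) || length(a) != ncol(W))
    stop("activation vector and weight matrix dimensions disagree",
         call. = FALSE)
  input <- drop(crossprod(W, a))           # input_j = sum_i w_ij a_i
  if (config$rule == "self_memory") input <- input + a
  fcm_threshold(input, config)
}

#' Simulate the FCM dynamics
#'
#' Iterates [propagate_step()] from the model's initial activation vector,
#' applying any clamps after every step (and to the initial row), until a
#' fixed point is reached (max-abs difference between consecutive states
#' below `fixed_point_tolerance`), a limit cycle is detected (a state, after
#' rounding to `state_rounding_digits`, repeats one seen within
#' `cycle_detection_horizon` previous steps), or `max_iterations` runs out.
#'
#' @param model an [fcm_model()].
#' @param clamps optional map construct index -> fixed value, merged over
#'   the model's own clamps (same format as in [fcm_model()]).
#' @return An object of class `fcm_trace`: list with `states` (a (T+1) x n
#'   matrix, row t+1 = activation after t steps), `verdict` (`"fixed_point"`,
#'   `"limit_cycle"` or `"max_iterations_reached"`), `period` (cycle period
#'   or `NA`), `iterations_run`, and the `config` used.
#' @export
#' @examples
#' m <- fcm_model(c(1, 0), matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE),
#'                sim_config(rule = "kosko"))
#' tr <- fcm_simulate(m)
#' tr$verdict
fcm_simulate <- function(model, clamps = NULL) {
  stopifnot(inherits(model, "fcm_model"))
  cfg <- model$config
  n <- length(model$a0)
  cl <- model$clamps
  extra <- normalize_clamps(clamps, n)
  if (length(extra)) cl[names(extra)] <- extra
  apply_clamps <- function(a) {
    if (length(cl)) a[as.integer(names(cl))] <- unname(cl)
    a
  }
  a <- apply_clamps(model$a0)
  states <- matrix(NA_real_, cfg$max_iterations + 1L, n)
  states[1L, ] <- a
  seen <- list(round(a, cfg$state_rounding_digits))
  verdict <- "max_iterations_reached"
  period <- NA_integer_
  t <- 0L
  while (t < cfg$max_iterations) {
    a_next <- apply_clamps(propagate_step(a, model$W, cfg))
    t <- t + 1L
    states[t + 1L, ] <- a_next
    if (max(abs(a_next - a)) < cfg$fixed_point_tolerance) {
      verdict <- "fixed_point"
      a <- a_next
      break
    }
    key <- round(a_next, cfg$state_rounding_digits)
    lookback <- seq.int(from = max(1L, length(seen) - cfg$cycle_detection_horizon + 1L),
                        to = length(seen))
    hit <- NA_integer_
    for (k in rev(lookback)) {
      if (isTRUE(all(seen[[k]] == key))) { hit <- k; break }
    }
    if (!is.na(hit)) {
      verdict <- "limit_cycle"
      period <- (t + 1L) - hit
      a <- a_next
      break
    }
    seen[[length(seen) + 1L]] <- key
    a <- a_next
  }
  structure(list(states = states[seq_len(t + 1L), , drop = FALSE],
                 verdict = verdict, period = period, iterations_run = t,
                 config = cfg),
            class = "fcm_trace")
}

#' @export
print.fcm_trace <- function(x, ...) {
  cat(sprintf("FCM trace: %d construct(s), %d iteration(s), verdict: %s%s\n",
              ncol(x$states), x$iterations_run, x$verdict,
              if (!is.na(x$period)) sprintf(" (period %d)", x$period) else ""))
  invisible(x)
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf("FCM model: %d node(s), %d edge(s), rule=%s, threshold=%s\n",
              length(x$a0), sum(x$W != 0), x$config$rule, x$config$threshold))
  invisible(x)
}

#' Export an iteration trace
#'
#' CSV layout: `iteration` column then one column per construct with the
#' canonical-frame activation to six decimals. The JSON variant bundles the
#' verdict and the simulation configuration alongside the full-precision
#' states.
#'
#' @param trace an `fcm_trace`.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @param construct_names optional column names (default `C1..Cn`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "json"),
                        construct_names = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(trace, "fcm_trace"))
  n <- ncol(trace$states)
  if (is.null(construct_names)) construct_names <- paste0("C", seq_len(n))
  if (format == "csv") {
    df <- data.frame(iteration = seq_len(nrow(trace$states)) - 1L,
                     round(trace$states, 6L))
    names(df) <- c("iteration", construct_names)
    write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  } else {
    jsonlite::write_json(
      list(states = trace$states, verdict = trace$verdict,
           period = trace$period, iterations_run = trace$iterations_run,
           construct_names = construct_names,
           config = unclass(trace$config)),
      path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}
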