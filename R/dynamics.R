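#' Ideal-Self activation vector
#'
#' @param grid a [repgrid()] with an `ideal_self` element.
#' @return numeric vector of canonical-frame ideal activations.
#' @export
ideal_vector <- function(grid) {
  stopifnot(inherits(grid, "repgrid"))
  rating_to_activation(grid$ratings[, role_index(grid, "ideal_self")])
}

#' Distance-to-ideal trajectories
#'
#' For every iteration of a simulated trace, computes each construct's
#' normalized distance to the Ideal-Self,
#' `d_i(t) = |a_i(t) - I_i| / 2` in [0, 1] (0 = at the ideal pole with full
#' intensity, 1 = at the opposite extreme), plus the unweighted mean across
#' constructs at each iteration. A construct counts as *achieved* when its
#' final distance is below the tolerance `tau`.
#'
#' Dilemmatic constructs (ideal at the midpoint) are included but flagged in
#' `dilemmatic`, since distance-to-ideal is semantically weak when no pole
#' is preferred.
#'
#' @param trace an `fcm_trace` from [fcm_simulate()].
#' @param ideal ideal activation vector, same length as the trace width.
#' @param tau achievement tolerance in (0, 1]; default `1/6`, half of one
#'   rating step on the normalized scale.
#' @return An object of class `fcm_dynamics`: list with `ideal`,
#'   `distances` ((T+1) x n matrix), `mean_distance` (length T+1),
#'   `achieved` (logical, per construct, at the final state), `dilemmatic`
#'   (logical) and `tau`.
#' @export
distance_trajectory <- function(trace, ideal, tau = 1 / 6) {
  stopifnot(inherits(trace, "fcm_trace"))
  ideal <- as.numeric(ideal)
  if (length(ideal) != ncol(trace$states))
    stop("ideal vector length does not match the trace", call. = FALSE)
  if (!(tau > 0 && tau <= 1))
    stop("tau must lie in (0, 1]", call. = FALSE)
  d <- abs(sweep(trace$states, 2L, ideal)) / 2
  structure(list(ideal = ideal,
                 distances = d,
                 mean_distance = rowMeans(d),
                 achieved = d[nrow(d), ] < tau,
                 dilemmatic = ideal == 0,
                 tau = tau),
            class = "fcm_dynamics")
}

#' @export
print.fcm_dynamics <- function(x, ...) {
  Tn <- nrow(x$distances) - 1L
  cat(sprintf(
    "PCS dynamics: %d construct(s), %d iteration(s)\n  mean distance to ideal: %.3f (start) -> %.3f (end)\n  achieved (d < %.3f): %d of %d\n",
    ncol(x$distances), Tn, x$mean_distance[1L],
    x$mean_distance[length(x$mean_distance)], x$tau,
    sum(x$achieved), length(x$achieved)))
  invisible(x)
}

#' Plot distance-to-ideal trajectories
#'
#' Iteration on the x-axis, normalized distance to the Ideal-Self on the
#' y-axis; one line per construct plus the mean in bold. The closer a curve
#' sits to the x-axis, the closer that construct is to the ideal.
#'
#' @param x an `fcm_dynamics`.
#' @param construct_names optional legend labels.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fcm_dynamics <- function(x, construct_names = NULL, ...) {
  n <- ncol(x$distances)
  iter <- seq_len(nrow(x$distances)) - 1L
  cols <- grDevices::hcl.colors(n, "Dark 3")
  graphics::matplot(iter, x$distances, type = "l", lty = 1L, col = cols,
                    ylim = c(0, 1), xlab = "iteration",
                    ylab = "distance to Ideal-Self", ...)
  graphics::lines(iter, x$mean_distance, lwd = 3L, col = "black")
  graphics::abline(h = x$tau, lty = 3L)
  if (!is.null(construct_names))
    graphics::legend("topright", legend = c(construct_names, "mean"),
                     col = c(cols, "black"), lty = 1L, cex = 0.7,
                     lwd = c(rep(1L, n), 3L))
  invisible(x)
}

#' Write the dynamics table to CSV
#'
#' Columns: `iteration`, one distance column per construct,
#' `mean_distance`.
#'
#' @param dyn an `fcm_dynamics`.
#' @param path output file.
#' @param construct_names optional column names (default `C1..Cn`).
#' @return `path`, invisibly.
#' @export
write_dynamics <- function(dyn, path, construct_names = NULL) {
  stopifnot(inherits(dyn, "fcm_dynamics"))
  n <- ncol(dyn$distances)
  if (is.null(construct_names)) construct_names <- paste0("C", seq_len(n))
  df <- data.frame(iteration = seq_len(nrow(dyn$distances)) - 1L,
                   round(dyn$distances, 6L),
                   mean_distance = round(dyn$mean_distance, 6L))
  names(df) <- c("iteration", construct_names, "mean_distance")
  write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Stability report for a simulated personal construct system
#'
#' Summarises what the simulation did to the system: the convergence
#' verdict, which constructs changed status between the first and last
#' state (pole sign flips, and midpoint constructs that resolved to a pole
#' — toward or away from the ideal), and which desired changes did not
#' happen (constructs discrepant at the start and not achieved at the end).
#'
#' @param trace an `fcm_trace`.
#' @param dyn the matching `fcm_dynamics` from [distance_trajectory()].
#' @param statuses optional `construct_status` data frame (from
#'   [classify_grid()] or [classify_construct()]) giving the t = 0 statuses;
#'   when omitted, discrepancy at t = 0 is inferred from the trace's first
#'   row and the ideal vector.
#' @return A list of class `stability_report` with fields `verdict`,
#'   `iterations_run`, `sign_changes` (data frame: construct, from, to),
#'   `resolved` (data frame: construct, to, toward_ideal) and
#'   `unachieved` (integer vector of desired-but-unachieved constructs).
#' @export
stability_report <- function(trace, dyn, statuses = NULL) {
  stopifnot(inherits(trace, "fcm_trace"), inherits(dyn, "fcm_dynamics"))
  if (ncol(trace$states) != ncol(dyn$distances))
    stop("trace and dynamics disagree on the number of constructs",
         call. = FALSE)
  first <- trace$states[1L, ]
  last <- trace$states[nrow(trace$states), ]
  s0 <- sign(first); sT <- sign(last)
  flipped <- which(s0 != 0 & sT != 0 & s0 != sT)
  resolved_idx <- which(s0 == 0 & sT != 0)
  if (is.null(statuses)) {
    discrepant0 <- (dyn$ideal != 0) & (s0 != sign(dyn$ideal))
  } else {
    discrepant0 <- statuses$status == "discrepant"
  }
  unachieved <- which(discrepant0 & !dyn$achieved)
  structure(list(
    verdict = trace$verdict,
    iterations_run = trace$iterations_run,
    sign_changes = data.frame(construct = flipped, from = s0[flipped],
                              to = sT[flipped]),
    resolved = data.frame(construct = resolved_idx,
                          to = sT[resolved_idx],
                          toward_ideal = sT[resolved_idx] ==
                            sign(dyn$ideal[resolved_idx]) &
                            dyn$ideal[resolved_idx] != 0),
    unachieved = unachieved
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report: %s after %d iteration(s)\n",
              x$verdict, x$iterations_run))
  if (nrow(x$sign_changes))
    cat("  pole flips:",
        paste(sprintf("construct %d (%+d -> %+d)", x$sign_changes$construct,
                      x$sign_changes$from, x$sign_changes$to),
              collapse = ", "), "\n")
  if (nrow(x$resolved))
    cat("  midpoint resolutions:",
        paste(sprintf("construct %d -> %+d (%s ideal)", x$resolved$construct,
                      x$resolved$to,
                      ifelse(x$resolved$toward_ideal, "toward", "away from")),
              collapse = ", "), "\n")
  if (length(x$unachieved)) {
    cat("  desired but unachieved:",
        paste("construct", x$unachieved, collapse = ", "), "\n")
  } else {
    cat("  all desired changes achieved\n")
  }
  invisible(x)
}
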