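# Independent oracles and shared fixtures for the suite.

# Naive propagation step: scalar double loop, written independently of
# propagate_step's vectorised path.
naive_step <- function(a, W, rule, threshold, lambda = 1) {
  n <- length(a)
  out <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(n)) if (i != j) s <- s + W[i, j] * a[i]
    if (rule == "self_memory") s <- s + a[j]
    out[j] <- switch(threshold,
                     tanh = tanh(lambda * s),
                     clamp = if (s > 1) 1 else if (s < -1) -1 else s,
                     sign = if (s > 0) 1 else if (s < 0) -1 else 0)
  }
  out
}

# Brute-force conflict enumeration straight from the definitions.
naive_conflicts <- function(W, a0, statuses) {
  n <- length(a0)
  res <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || W[i, j] == 0) next
    gi <- statuses$desired_direction[i]
    gj <- statuses$desired_direction[j]
    Ij <- statuses$ideal_activation[j]
    kind <- NA_character_
    if (statuses$status[i] == "discrepant" &&
        statuses$status[j] == "congruent" &&
        sign(Ij) != 0 && sign(W[i, j] * gi) == -sign(Ij))
      kind <- "goal_harms_content"
    if (statuses$status[i] == "congruent" &&
        statuses$status[j] == "discrepant" &&
        sign(gj) != 0 && sign(W[i, j] * a0[i]) == -sign(gj))
      kind <- "content_blocks_goal"
    if (!is.na(kind))
      res <- rbind(res, data.frame(source = i, target = j, kind = kind))
  }
  if (is.null(res))
    data.frame(source = integer(), target = integer(), kind = character())
  else res[order(res$source, res$target), ]
}

# Minimal two-element grid (Self-Now, Ideal-Self) from rating vectors.
tiny_grid <- function(self, ideal, poles = NULL) {
  n <- length(self)
  if (is.null(poles))
    poles <- data.frame(left_pole = sprintf("L%d", seq_len(n)),
                        right_pole = sprintf("R%d", seq_len(n)))
  repgrid(poles,
          data.frame(label = c("self", "ideal"),
                     role = c("self_now", "ideal_self")),
          cbind(self, ideal))
}

# Three-construct relapse case: a discrepant goal (construct 1) blocked by
# a contented construct (2) and weakly supported by another (3). With the
# self-memory rule and the clamp threshold every state is exact 1/3
# arithmetic, so the whole trajectory can be iterated by hand.
relapse_case <- function() {
  grid <- tiny_grid(self = c(1, 1, 7), ideal = c(7, 1, 7),
                    poles = data.frame(
                      left_pole = c("inactive", "enjoys comfort", "supported"),
                      right_pole = c("active", "ascetic", "unsupported")))
  s <- matrix(0L, 3, 3)
  s[2, 1] <- 2L   # holding construct 2 at its pole pushes the goal back
  s[3, 1] <- -1L  # construct 3 mildly supports the goal
  imp <- impgrid(grid$constructs, s)
  cfg <- sim_config(rule = "self_memory", threshold = "clamp")
  list(grid = grid, imp = imp, model = build_fcm(grid, imp, cfg))
}
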