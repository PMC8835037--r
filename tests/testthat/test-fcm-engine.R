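test_that("the activation vector comes straight from the Self-Now column", {
  we <- worked_example()
  a0 <- build_activation_vector(we$grid)
  expect_identical(a0[1], -1)          # "very" at the overweight pole
  expect_equal(a0[2], -1 / 3)
  expect_identical(a0[5], 0)           # undefined on healthy vs unhealthy

  g <- tiny_grid(c(1, 4, 7), c(7, 4, 1))
  expect_equal(build_activation_vector(g), c(-1, 0, 1))
  expect_equal(build_activation_vector(tiny_grid(c(4, 4), c(4, 4))), c(0, 0))
})

test_that("weight matrix encodes the elicitation frame of the worked row", {
  we <- worked_example()
  W <- build_weight_matrix(we$imp, we$grid)
  # construct 1 sits at the left pole (a0 = -1), so the hypothesized change
  # runs rightward (d = +1): stored scores -3/-3/-2 become full-strength
  # weights toward the stated poles
  expect_equal(W[1, c(4, 5, 6)], c(-1, -1, -2 / 3))
  expect_equal(sum(W[1, ] != 0), 3)
  expect_true(all(diag(W) == 0))
  expect_true(all(abs(W) <= 1))

  # same scores from a source at the opposite pole are negated
  g2 <- we$grid
  g2$ratings[1, 1] <- 7L  # Self-Now now at the right pole, d = -1
  W2 <- build_weight_matrix(we$imp, g2)
  expect_equal(W2[1, ], -W[1, ])

  # a zero implications grid gives the zero matrix
  imp0 <- impgrid(we$grid$constructs, matrix(0L, 12, 12))
  expect_true(all(build_weight_matrix(imp0, we$grid) == 0))
})

test_that("a source with no defined change direction is a frame error", {
  g <- tiny_grid(c(4, 1), c(4, 7))
  imp <- impgrid(g$constructs, matrix(c(0L, 0L, 2L, 0L), 2, 2))
  expect_error(build_weight_matrix(imp, g), "construct 1")
  # midpoint self with an off-midpoint ideal falls back to the desired side
  g2 <- tiny_grid(c(4, 1), c(1, 7))
  W <- build_weight_matrix(imp, g2)
  expect_equal(W[1, 2], -2 / 3)  # d = sign(ideal - self) = -1
})

test_that("threshold functions are the documented squashers", {
  for (th in c("tanh", "clamp", "sign"))
    expect_identical(fcm_threshold(0, sim_config(threshold = th)), 0)
  expect_equal(fcm_threshold(1, sim_config(threshold = "tanh")),
               0.76159, tolerance = 1e-5)
  expect_equal(fcm_threshold(1, sim_config(threshold = "tanh", lambda = 2)),
               tanh(2))
  expect_identical(fcm_threshold(2.5, sim_config(threshold = "clamp")), 1)
  expect_identical(fcm_threshold(-0.3, sim_config(threshold = "clamp")), -0.3)
  expect_identical(fcm_threshold(-2, sim_config(threshold = "sign")), -1)
  expect_error(fcm_threshold(Inf, sim_config()), "non-finite")
})

test_that("propagate_step matches closed forms on tiny systems", {
  # zero matrix, kosko: everything dies in one step
  cfg <- sim_config(rule = "kosko")
  expect_equal(propagate_step(c(0.5, -0.2), matrix(0, 2, 2), cfg), c(0, 0))
  # zero matrix, self-memory: each entry squashed through tanh
  cfgm <- sim_config(rule = "self_memory")
  expect_equal(propagate_step(c(0.5, 0.5), matrix(0, 2, 2), cfgm),
               rep(0.46212, 2), tolerance = 1e-5)
  # 2-node chain: node 1 has no inputs, node 2 receives tanh(1)
  W <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(propagate_step(c(1, 0), W, cfg), c(0, 0.76159),
               tolerance = 1e-5)
  expect_error(propagate_step(c(1, 0, 0), W, cfg), "dimensions")
})

test_that("propagate_step agrees with the naive double-loop oracle", {
  set.seed(42)
  for (rule in c("kosko", "self_memory")) {
    for (th in c("tanh", "clamp", "sign")) {
      cfg <- sim_config(rule = rule, threshold = th, lambda = 1.3)
      for (rep in 1:200) {
        n <- sample(2:8, 1)
        W <- matrix(runif(n * n, -1, 1), n, n); diag(W) <- 0
        a <- runif(n, -1, 1)
        expect_lt(max(abs(propagate_step(a, W, cfg) -
                          naive_step(a, W, rule, th, 1.3))), 1e-12)
      }
    }
  }
})

test_that("frame consistency: a unit push of the source moves targets as elicited", {
  set.seed(7)
  lin <- sim_config(rule = "kosko", threshold = "clamp")
  for (rep in 1:50) {
    cfg <- generator_config(n_constructs = sample(3:8, 1), n_elements = 4,
                            implication_density = 0.5, seed = rep)
    cs <- random_case(cfg)
    W <- build_weight_matrix(cs$imp, cs$grid)
    a0 <- build_activation_vector(cs$grid)
    ideal <- ideal_vector(cs$grid)
    d <- -sign(a0); d[d == 0] <- sign(ideal - a0)[d == 0]
    for (i in seq_along(a0)) {
      a <- numeric(length(a0)); a[i] <- d[i]
      moved <- propagate_step(a, W, lin)
      js <- setdiff(which(cs$imp$scores[i, ] != 0), i)
      expect_identical(sign(moved[js]), sign(as.numeric(cs$imp$scores[i, js])))
    }
  }
})

test_that("simulation stops at fixed points, cycles and the budget", {
  # zero matrix under kosko collapses to the zero fixed point
  m0 <- fcm_model(c(1, -0.5, 0.3), matrix(0, 3, 3),
                  sim_config(rule = "kosko"))
  tr0 <- fcm_simulate(m0)
  expect_identical(tr0$verdict, "fixed_point")
  expect_lte(tr0$iterations_run, 2L)
  expect_equal(tr0$states[nrow(tr0$states), ], c(0, 0, 0))

  # antagonistic pair under the sign threshold: period-2 cycle
  W <- matrix(c(0, -1, -1, 0), 2, 2)
  mc <- fcm_model(c(1, 1), W, sim_config(rule = "kosko", threshold = "sign"))
  trc <- fcm_simulate(mc)
  expect_identical(trc$verdict, "limit_cycle")
  expect_identical(trc$period, 2L)
  expect_equal(trc$states[2, ], c(-1, -1))
  expect_equal(trc$states[3, ], c(1, 1))

  # 2-node chain passes through (0, tanh 1) then reaches the origin
  Wc <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  mch <- fcm_model(c(1, 0), Wc, sim_config(rule = "kosko"))
  trch <- fcm_simulate(mch)
  expect_identical(trch$verdict, "fixed_point")
  expect_equal(trch$states[2, ], c(0, tanh(1)))
  expect_equal(trch$states[nrow(trch$states), ], c(0, 0))

  # iteration budget is honoured: node 1 drifts down 0.1 per step, so five
  # iterations end mid-flight with neither fixed point nor cycle
  mb <- fcm_model(c(1, 1), matrix(c(0, 0, -0.1, 0), 2, 2, byrow = TRUE),
                  sim_config(rule = "self_memory", threshold = "clamp",
                             max_iterations = 5))
  expect_identical(fcm_simulate(mb)$verdict, "max_iterations_reached")
  expect_identical(fcm_simulate(mb)$iterations_run, 5L)
})

test_that("every trace entry stays inside [-1, 1] for all thresholds", {
  set.seed(11)
  for (th in c("tanh", "clamp", "sign")) {
    for (rule in c("kosko", "self_memory")) {
      for (rep in 1:20) {
        n <- sample(2:8, 1)
        W <- matrix(runif(n * n, -1, 1), n, n); diag(W) <- 0
        m <- fcm_model(runif(n, -1, 1), W,
                       sim_config(rule = rule, threshold = th,
                                  max_iterations = 30))
        tr <- fcm_simulate(m)
        expect_true(all(abs(tr$states) <= 1))
      }
    }
  }
})

test_that("trajectories are odd under global negation (tanh and sign)", {
  set.seed(13)
  for (th in c("tanh", "sign")) {
    for (rule in c("kosko", "self_memory")) {
      for (rep in 1:15) {
        n <- sample(2:6, 1)
        W <- matrix(runif(n * n, -1, 1), n, n); diag(W) <- 0
        a0 <- runif(n, -1, 1)
        cfg <- sim_config(rule = rule, threshold = th, max_iterations = 25)
        tp <- fcm_simulate(fcm_model(a0, W, cfg))
        tn <- fcm_simulate(fcm_model(-a0, W, cfg))
        expect_identical(tp$verdict, tn$verdict)
        expect_equal(tn$states, -tp$states, tolerance = 1e-12)
      }
    }
  }
})

test_that("a constructed fixed point persists", {
  # self-memory + clamp: a state with zero net input is a fixed point; for
  # this antisymmetric W only the origin qualifies unsaturated
  W <- matrix(c(0, 0.5, -0.5, 0), 2, 2, byrow = TRUE)
  m <- fcm_model(c(0, 0), W, sim_config(rule = "self_memory",
                                        threshold = "clamp"))
  tr <- fcm_simulate(m)
  expect_identical(tr$verdict, "fixed_point")
  expect_true(all(abs(tr$states) < 1e-12))

  # saturated mutual support is a fixed point under clamp
  Ws <- matrix(c(0, 1, 1, 0), 2, 2)
  ms <- fcm_model(c(1, 1), Ws, sim_config(rule = "self_memory",
                                          threshold = "clamp"))
  trs <- fcm_simulate(ms)
  expect_identical(trs$verdict, "fixed_point")
  expect_true(all(trs$states == 1))
})

test_that("clamped constructs hold their value in every trace row, exactly", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 5
    W <- matrix(runif(n * n, -1, 1), n, n); diag(W) <- 0
    m <- fcm_model(runif(n, -1, 1), W, sim_config(max_iterations = 20),
                   clamps = c(`2` = 0.7, `5` = -1))
    tr <- fcm_simulate(m)
    expect_true(all(tr$states[, 2] == 0.7))
    expect_true(all(tr$states[, 5] == -1))
  }
  # clamps passed at simulate time override the model's
  m2 <- fcm_model(c(0, 0), matrix(0, 2, 2), clamps = c(`1` = 0.5))
  tr2 <- fcm_simulate(m2, clamps = c(`1` = -0.5))
  expect_true(all(tr2$states[, 1] == -0.5))
})

test_that("trace export writes the documented CSV and JSON layouts", {
  m <- fcm_model(c(1, 0), matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE),
                 sim_config(rule = "kosko"))
  tr <- fcm_simulate(m)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, p, "csv", construct_names = c("goal", "follower"))
  got <- utils::read.csv(p)
  expect_identical(names(got), c("iteration", "goal", "follower"))
  expect_identical(got$iteration[1], 0L)
  expect_equal(got$follower[2], round(tanh(1), 6))

  pj <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, pj, "json")
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(back$verdict, "fixed_point")
  expect_equal(back$states, tr$states)
})
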