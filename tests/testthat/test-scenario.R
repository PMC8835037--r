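test_that("conflict detection matches the worked case narrative", {
  we <- worked_example()
  m <- build_fcm(we$grid, we$imp)
  st <- classify_grid(we$grid)
  cf <- detect_conflicts(m, st)
  # the contented "enjoys eating" construct (3) receives goal_harms_content
  # edges from the eating-control / health / willpower / healthy-eating goals
  harms <- cf[cf$kind == "goal_harms_content", ]
  expect_setequal(harms$source, c(2L, 5L, 7L, 8L))
  expect_true(all(harms$target == 3L))
  # and holding that pole blocks those same goals
  blocks <- cf[cf$kind == "content_blocks_goal", ]
  expect_true(all(blocks$source == 3L))
  expect_setequal(blocks$target, c(2L, 5L, 7L, 8L))
  # ordering: severity descending, ties by (source, target)
  expect_true(all(diff(cf$severity) <= 0))
  same <- which(diff(cf$severity) == 0)
  expect_true(all(cf$source[same] < cf$source[same + 1] |
                  (cf$source[same] == cf$source[same + 1] &
                   cf$target[same] < cf$target[same + 1])))
})

test_that("a zero weight matrix yields no conflicts", {
  m <- fcm_model(c(-1, 1), matrix(0, 2, 2))
  st <- classify_construct(c(1, 7), c(7, 7))
  expect_identical(nrow(detect_conflicts(m, st)), 0L)
})

test_that("conflict detection equals brute-force enumeration on random cases", {
  set.seed(31)
  for (rep in 1:40) {
    cfg <- generator_config(n_constructs = sample(3:8, 1), n_elements = 3,
                            implication_density = 0.5,
                            congruent_fraction = 0.4,
                            dilemmatic_fraction = 0.2, seed = 1000 + rep)
    cs <- random_case(cfg)
    m <- build_fcm(cs$grid, cs$imp)
    st <- classify_grid(cs$grid)
    got <- detect_conflicts(m, st)
    got <- got[order(got$source, got$target), c("source", "target", "kind")]
    rownames(got) <- NULL
    want <- naive_conflicts(m$W, m$a0, st)
    rownames(want) <- NULL
    expect_equal(as.data.frame(got), want)
  }
})

test_that("the empty scenario is the identity and models are never mutated", {
  we <- worked_example()
  m <- build_fcm(we$grid, we$imp)
  m2 <- apply_scenario(m, we$grid, we$imp, scenario_spec())
  expect_equal(m2$a0, m$a0)
  expect_equal(m2$W, m$W)
  snapshot <- unclass(m)
  spec <- scenario_spec(perturbations = c(`1` = 1),
                        clamps = c(`2` = 0.5),
                        weight_edits = data.frame(source = 1, target = 4,
                                                  score = 0))
  s1 <- apply_scenario(m, we$grid, we$imp, spec)
  s2 <- apply_scenario(m, we$grid, we$imp, spec)
  expect_equal(unclass(m), snapshot)       # input untouched
  expect_equal(s1$a0, s2$a0)               # application is pure
  expect_equal(s1$W, s2$W)
})

test_that("perturbations only touch a0 and edits only touch W", {
  we <- worked_example()
  m <- build_fcm(we$grid, we$imp)
  p <- apply_scenario(m, we$grid, we$imp,
                      scenario_spec(perturbations = c(`1` = 1, `4` = -1)))
  expect_equal(p$W, m$W)
  expect_equal(p$a0[c(1, 4)], c(1, -1))
  expect_equal(p$a0[-c(1, 4)], m$a0[-c(1, 4)])

  e <- apply_scenario(m, we$grid, we$imp,
                      scenario_spec(weight_edits = data.frame(
                        source = c(1, 2), target = c(4, 3),
                        score = c(0, -1))))
  expect_equal(e$a0, m$a0)
  expect_identical(e$W[1, 4], 0)
  expect_equal(e$W[2, 3], -1 / 3)  # d_2 = +1, stored score -1
  untouched <- m$W; untouched[1, 4] <- 0; untouched[2, 3] <- -1 / 3
  expect_equal(e$W, untouched)

  expect_error(scenario_spec(weight_edits = data.frame(source = 1, target = 1,
                                                       score = 2)),
               "diagonal")
  expect_error(apply_scenario(m, we$grid, we$imp,
                              scenario_spec(perturbations = c(`1` = 2))),
               "\\[-1, 1\\]")
})

test_that("removing a flagged edge never increases the conflict count", {
  set.seed(37)
  for (rep in 1:15) {
    cfg <- generator_config(n_constructs = 6, n_elements = 3,
                            implication_density = 0.6,
                            congruent_fraction = 0.5, seed = 2000 + rep)
    cs <- random_case(cfg)
    m <- build_fcm(cs$grid, cs$imp)
    st <- classify_grid(cs$grid)
    cf <- detect_conflicts(m, st)
    if (!nrow(cf)) next
    before <- nrow(cf)
    m2 <- apply_scenario(m, cs$grid, cs$imp, scenario_spec(
      weight_edits = data.frame(source = cf$source[1], target = cf$target[1],
                                score = 0)))
    expect_lte(nrow(detect_conflicts(m2, st)), before - 1L)
  }
})

test_that("a one-shot behaviour change relapses while an implication edit holds", {
  rc <- relapse_case()
  tau <- 0.2
  baseline <- fcm_simulate(rc$model)
  bdyn <- distance_trajectory(baseline, ideal_vector(rc$grid), tau = tau)
  expect_identical(baseline$verdict, "fixed_point")
  expect_identical(bdyn$distances[1, 1], 1)   # goal at the opposite extreme
  expect_false(bdyn$achieved[1])

  # the blocking edge 2 -> 1 is the single detected conflict
  st <- classify_grid(rc$grid)
  cf <- detect_conflicts(rc$model, st)
  expect_identical(nrow(cf), 1L)
  expect_identical(cf$kind, "content_blocks_goal")
  expect_identical(c(cf$source, cf$target), c(2L, 1L))

  # scenario A: push the goal to its ideal once, change nothing else;
  # exact hand iteration: 1, 2/3, 1/3, 0, -1/3, -2/3, -1, -1, ...
  pert <- scenario_spec(perturbations = c(`1` = 1))
  mA <- apply_scenario(rc$model, rc$grid, rc$imp, pert)
  trA <- fcm_simulate(mA)
  expect_equal(trA$states[1:8, 1], c(1, 2/3, 1/3, 0, -1/3, -2/3, -1, -1))
  dynA <- distance_trajectory(trA, ideal_vector(rc$grid), tau = tau)
  cmpA <- compare_scenarios(list(trace = baseline, dynamics = bdyn),
                            list(trace = trA, dynamics = dynA))
  expect_true(cmpA$constructs$relapse[1])
  expect_false(cmpA$constructs$scenario_achieved[1])

  # scenario B: additionally break the blocking implication
  edit <- scenario_spec(perturbations = c(`1` = 1),
                        weight_edits = data.frame(source = 2, target = 1,
                                                  score = 0))
  mB <- apply_scenario(rc$model, rc$grid, rc$imp, edit)
  trB <- fcm_simulate(mB)
  dynB <- distance_trajectory(trB, ideal_vector(rc$grid), tau = tau)
  cmpB <- compare_scenarios(list(trace = baseline, dynamics = bdyn),
                            list(trace = trB, dynamics = dynB))
  expect_true(cmpB$constructs$scenario_achieved[1])
  expect_false(cmpB$constructs$relapse[1])
  expect_identical(dynB$distances[nrow(dynB$distances), 1], 0)
  # and the conflict is gone
  expect_identical(nrow(detect_conflicts(mB, st)), 0L)

  # identical runs compare with all-zero deltas
  cmp0 <- compare_scenarios(list(trace = baseline, dynamics = bdyn),
                            list(trace = baseline, dynamics = bdyn))
  expect_equal(cmp0$constructs$scenario_final, cmp0$constructs$baseline_final)
  expect_false(any(cmp0$constructs$relapse))
})

test_that("scenario specs round-trip through JSON", {
  spec <- scenario_spec(perturbations = c(`1` = 1, `3` = -0.5),
                        clamps = c(`2` = 0.25),
                        weight_edits = data.frame(source = 2L, target = 1L,
                                                  score = 0L))
  p <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(spec, p)
  back <- read_scenario_json(p)
  expect_equal(back$perturbations, spec$perturbations)
  expect_equal(back$clamps, spec$clamps)
  expect_equal(back$weight_edits, spec$weight_edits)
})
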