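test_that("rw_update does one-step compound-cue arithmetic", {
  st <- list(V = setNames(numeric(0), character(0)), alpha = 0.2,
             lambda_good = 1, lambda_bad = -2)
  st <- rw_update(st, c("shape:circle", "color:blue"), "good")
  expect_equal(unname(st$V[c("shape:circle", "color:blue")]), c(0.2, 0.2))

  # with sum(V) = 0.4 and an outcome asymptote of 0, each displayed cue
  # moves by alpha * (0 - 0.4) = -0.08
  st0 <- list(V = c(`shape:circle` = 0.3, `color:blue` = 0.1), alpha = 0.2,
              lambda_good = 1, lambda_bad = 0)
  st0 <- rw_update(st0, c("shape:circle", "color:blue"), "bad")
  expect_equal(unname(st0$V), c(0.3 - 0.08, 0.1 - 0.08))

  # non-displayed cues unchanged
  st2 <- list(V = c(`shape:star` = 0.5), alpha = 0.2, lambda_good = 1,
              lambda_bad = -2)
  st2 <- rw_update(st2, "color:blue", "good")
  expect_equal(unname(st2$V["shape:star"]), 0.5)
})

test_that("relative validity emerges over a long experiment-1 stream", {
  # 500 feedback events: reliable cue perfectly valid, unreliable 0.78-valid
  withr::with_seed(123, {
    st <- list(V = setNames(numeric(0), character(0)), alpha = 0.2,
               lambda_good = 1, lambda_bad = -2)
    for (i in 1:500) {
      good <- runif(1) < 0.5
      congruent <- runif(1) < 0.78
      r_cue <- if (good) "shape:circle" else "shape:star"
      u_cue <- if (xor(good, !congruent)) "color:blue" else "color:yellow"
      st <- rw_update(st, c(r_cue, u_cue), if (good) "good" else "bad")
    }
    r_diff <- st$V[["shape:circle"]] - st$V[["shape:star"]]
    u_diff <- st$V[["color:blue"]] - st$V[["color:yellow"]]
    expect_gt(r_diff, 0)
    expect_gt(r_diff, 4 * abs(u_diff))
    # compound predictions (not individual strengths) settle between the
    # asymptotes; allow slack for cue-sharing transients
    expect_true(all(is.finite(st$V)))
    for (r_cue in c("shape:circle", "shape:star")) {
      for (u_cue in c("color:blue", "color:yellow")) {
        pred <- st$V[[r_cue]] + st$V[[u_cue]]
        expect_gte(pred, -2.5)
        expect_lte(pred, 1.5)
      }
    }
  })
})

test_that("decision policies behave at their limits", {
  # random archetype attacks with probability ~0.5
  agent <- make_subject(archetype_random(), 1)
  phen <- list(reliable_value = "G1", reliable_polarity = "+",
               unreliable_value = "U+", reliable_display = "circle",
               unreliable_display = "blue", reliable_dim = "shape",
               unreliable_dim = "color")
  withr::with_seed(1, {
    hits <- mean(vapply(1:2000, function(i) agent_decide(agent, phen), TRUE))
  })
  expect_gt(hits, 0.45)
  expect_lt(hits, 0.55)

  # temperature -> 0 with a positive prediction attacks almost surely
  cold <- make_subject(archetype_rw(temperature = 1e-9), 1)
  cold$V <- c(`shape:circle` = 0.5, `color:blue` = 0.1)
  withr::with_seed(2, {
    expect_true(all(vapply(1:50, function(i) agent_decide(cold, phen), TRUE)))
  })
})

test_that("key-trait decisions depend only on the unreliable value", {
  agent <- make_subject(archetype_key_trait(), 1)
  # feed an experiment-3-like stream of feedback
  comm <- build_training_community(3)
  prey <- preycat:::expand_community(comm)
  tm <- attr(comm, "treatment")
  for (i in seq_len(nrow(prey))) {
    agent_learn(agent, preycat:::phenotype_at(prey, i, tm),
                prey$profitability[i])
  }
  vals <- paste0(rep(c("G", "B"), each = 4), 1:4)
  decide_for <- function(v, u) {
    agent_decide(agent, list(reliable_value = v,
                             reliable_polarity = substr(v, 1, 1),
                             unreliable_value = u,
                             reliable_display = v, unreliable_display = u,
                             reliable_dim = "shape", unreliable_dim = "color"))
  }
  for (u in c("U+", "U-")) {
    decisions <- vapply(vals, decide_for, TRUE, u = u)
    expect_length(unique(decisions), 1L)
  }
  # tallies favor U+ after a congruent stream
  expect_true(decide_for("B1", "U+"))
  expect_false(decide_for("G1", "U-"))
})

test_that("memorizer respects capacity with least-recently-reinforced
           eviction", {
  agent <- make_subject(archetype_memorizer(capacity = 4), 1)
  phen <- function(i) list(reliable_value = paste0("G", i),
                           reliable_polarity = "+", unreliable_value = "U+",
                           reliable_display = paste0("shape", i),
                           unreliable_display = "blue",
                           reliable_dim = "shape", unreliable_dim = "color")
  for (i in 1:6) agent_learn(agent, phen(i), "good")
  expect_length(agent$table, 4L)
  expect_setequal(names(agent$table),
                  c("shape3|blue", "shape4|blue", "shape5|blue",
                    "shape6|blue"))
  # reinforcing an old key moves it to the back of the eviction queue
  agent_learn(agent, phen(3), "good")
  agent_learn(agent, phen(7), "good")
  expect_true("shape3|blue" %in% names(agent$table))
  expect_false("shape4|blue" %in% names(agent$table))
})

test_that("a capacity-4 memorizer in experiment 3 mostly decides by
           fallback", {
  agent <- make_subject(archetype_memorizer(capacity = 4), 2)
  comm <- build_training_community(3)
  rec <- run_training_trial(comm, agent, rng_seed = 21)
  expect_lte(length(agent$table), 4L)
  # at most 4 of the 16 phenotypes can be known
  tc <- build_test_community(treatment_map(3, 1))
  keys <- paste(tc$reliable_display, tc$unreliable_display, sep = "|")
  expect_gte(sum(!keys %in% names(agent$table)), 4L)
})

test_that("identical archetype and seeds reproduce behavior streams", {
  for (kind in c("rw_learner", "key_trait", "memorizer", "human_like",
                 "random")) {
    r1 <- sim_records(kind, experiments = 2, nsub = 2, seed0 = 5)
    r2 <- sim_records(kind, experiments = 2, nsub = 2, seed0 = 5)
    expect_identical(r1, r2)
  }
})

test_that("agent_reset clears learned state", {
  agent <- make_subject(archetype_human_like(), 3)
  run_training_trial(build_training_community(2), agent, rng_seed = 13)
  expect_gt(length(agent$table), 0L)
  agent_reset(agent)
  expect_identical(agent_state(agent),
                   list(table = list(), recency = character(0),
                        utally = list()))
})

test_that("unknown archetypes are rejected", {
  expect_error(make_subject("bayesian"), "unknown archetype")
  expect_error(archetype_memorizer(fallback = "psychic"))
})
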