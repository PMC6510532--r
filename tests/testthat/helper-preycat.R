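# Shared fixtures and independent oracles for the test suite. All fixtures
# are generated in code; nothing is read from disk.

# degenerate archetypes used as stub agents
always_attacker <- function() preycat::archetype_random(p_attack = 1)
never_attacker <- function() preycat::archetype_random(p_attack = 0)

# Simulate a miniature study: `nsub` subjects of one archetype, each running
# the given experiments (order = position in `experiments`), with treatments
# cycling 1..4. Returns the tidy record table.
sim_records <- function(archetype, experiments = 1L, nsub = 4L, seed0 = 1L) {
  recs <- list()
  for (s in seq_len(nsub)) {
    agent <- preycat::make_subject(archetype, seed0 + s)
    for (j in seq_along(experiments)) {
      e <- experiments[j]
      tm <- preycat::treatment_map(e, 1L + (s - 1L) %% 4L)
      preycat::agent_reset(agent)
      tr <- preycat::run_training_trial(
        preycat::build_training_community(e, tm), agent,
        rng_seed = seed0 * 1000L + 37L * s + 2L * j)
      te <- preycat::run_test_trial(
        preycat::build_test_community(tm), agent,
        rng_seed = seed0 * 1000L + 37L * s + 2L * j + 1L)
      tr$order <- j; te$order <- j
      tr$subject_id <- sprintf("S%02d", s)
      te$subject_id <- sprintf("S%02d", s)
      recs[[length(recs) + 1L]] <- rbind(tr, te)
    }
  }
  do.call(rbind, recs)
}

# Brute-force iterative grid search maximizing the Bernoulli-logit
# likelihood over two coefficients; independent of glm/IRLS.
grid_logit_2par <- function(y, x1, x2, lim = 8, steps = 41L, rounds = 8L) {
  ll <- function(b1, b2) {
    eta <- b1 * x1 + b2 * x2
    sum(y * eta - log1p(exp(eta)))
  }
  c1 <- c2 <- 0
  half <- lim
  for (r in seq_len(rounds)) {
    g1 <- seq(c1 - half, c1 + half, length.out = steps)
    g2 <- seq(c2 - half, c2 + half, length.out = steps)
    vals <- outer(g1, g2, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    c1 <- g1[best[1]]; c2 <- g2[best[2]]
    half <- half * 2 / (steps - 1) * 2  # keep neighbours of the best point
  }
  c(c1, c2)
}

# Build an analysis table with the real test-community design (focal rows
# per experiment) but attacks left unset; used to simulate directly from
# the model form.
design_table <- function(nsub = 8L, experiments = 1:5) {
  rows <- list()
  for (e in experiments) {
    tc <- preycat::build_test_community(preycat::treatment_map(e, 1L))
    prey <- preycat:::expand_community(tc)
    keep <- prey$reliable_value %in% intersect(
      preycat:::focal_value_set(e), preycat:::training_value_set(e))
    prey <- prey[keep, , drop = FALSE]
    for (s in seq_len(nsub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", s), experiment_id = e, trial = "test",
        order = ((s + e) %% length(experiments)) + 1L,
        reliable_value = prey$reliable_value,
        reliable_polarity = prey$reliable_polarity,
        unreliable_value = prey$unreliable_value,
        attacked = FALSE, stringsAsFactors = FALSE)
    }
  }
  preycat::prepare_table(do.call(rbind, rows))
}

# One default-configuration study, computed once and shared across test
# files (the acceptance criteria and several study tests all consume it).
.preycat_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.preycat_cache$study)) {
    .preycat_cache$study <- preycat::run_study(
      preycat::study_config(master_seed = 314159L))
  }
  .preycat_cache$study
}
default_report <- function() {
  if (is.null(.preycat_cache$report)) {
    .preycat_cache$report <- preycat::reproduce_report(default_study()$records)
  }
  .preycat_cache$report
}
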