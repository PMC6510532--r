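# Foraging game mechanics: life-bar dynamics, pretraining, training trials
# with feedback, and feedback-free test trials.

#' Game configuration
#'
#' Life units are arbitrary; only the ratios are meaningful. Attacking a bad
#' prey costs twice what a good prey yields. The training trial starts with
#' enough life to absorb eight bad attacks in a row; pretraining starts low
#' so the subject dies after four (all pretraining prey are bad).
#'
#' @param grid_size Number of prey per trial (default 36).
#' @param max_training_attacks Attack cap in feedback trials (default 18,
#'   half the grid).
#' @param good_gain Life gained per good prey attacked (default 1).
#' @param bad_loss Life lost per bad prey attacked; must equal
#'   `2 * good_gain` (default 2).
#' @param training_start_life Starting life in training; must equal
#'   `8 * bad_loss`.
#' @param pretraining_start_life Starting life in pretraining; must equal
#'   `4 * bad_loss`.
#' @return A `game_config` list.
#' @export
game_config <- function(grid_size = 36L, max_training_attacks = 18L,
                        good_gain = 1, bad_loss = 2,
                        training_start_life = 16,
                        pretraining_start_life = 8) {
  if (bad_loss != 2 * good_gain) {
    stop("bad_loss must be twice good_gain (2:1 cost:benefit ratio)")
  }
  if (training_start_life != 8 * bad_loss) {
    stop("training_start_life must allow exactly 8 bad attacks before death")
  }
  if (pretraining_start_life != 4 * bad_loss) {
    stop("pretraining_start_life must allow exactly 4 bad attacks before death")
  }
  structure(list(grid_size = as.integer(grid_size),
                 max_training_attacks = as.integer(max_training_attacks),
                 good_gain = good_gain, bad_loss = bad_loss,
                 training_start_life = training_start_life,
                 pretraining_start_life = pretraining_start_life),
            class = "game_config")
}

new_game_state <- function(start_life) {
  list(life = start_life, attacks_made = 0L, alive = start_life > 0)
}

#' Apply an attack outcome to the game state
#'
#' Good prey raise the life bar by `good_gain`; bad prey lower it by
#' `bad_loss`, floored at zero, at which point the subject is dead. Life
#' never changes between attacks.
#'
#' @param state A game state list (`life`, `attacks_made`, `alive`).
#' @param outcome `"good"` or `"bad"`.
#' @param config A [game_config()].
#' @return The updated state.
#' @export
apply_outcome <- function(state, outcome, config = game_config()) {
  if (!state$alive) stop("cannot apply an outcome to a dead state")
  outcome <- match.arg(outcome, c("good", "bad"))
  delta <- if (outcome == "good") config$good_gain else -config$bad_loss
  state$life <- max(0, state$life + delta)
  state$attacks_made <- state$attacks_made + 1L
  state$alive <- state$life > 0
  state
}

# Expand a community spec into one row per prey.
expand_community <- function(spec) {
  idx <- rep.int(seq_len(nrow(spec)), spec$abundance)
  prey <- as.data.frame(spec)[idx, c("reliable_value", "reliable_polarity",
                                     "unreliable_value", "profitability",
                                     "reliable_display", "unreliable_display",
                                     "focal"), drop = FALSE]
  rownames(prey) <- NULL
  prey
}

phenotype_at <- function(prey, i, treatment) {
  list(reliable_value = prey$reliable_value[i],
       reliable_polarity = prey$reliable_polarity[i],
       unreliable_value = prey$unreliable_value[i],
       reliable_display = prey$reliable_display[i],
       unreliable_display = prey$unreliable_display[i],
       reliable_dim = treatment$reliable_dim,
       unreliable_dim = treatment$unreliable_dim)
}

# Core presentation loop shared by all trial types. Prey are presented
# sequentially in a random permutation of the community multiset; the agent
# decides attack/skip per prey and skipped prey are not revisited (the
# sequential abstraction of the on-screen grid). Every presented prey yields
# one record; prey never presented (trial ended first) yield none.
sim_trial <- function(community, agent, config, rng_seed, trial) {
  treatment <- attr(community, "treatment")
  prey <- expand_community(community)
  n <- nrow(prey)
  if (trial != "test" && n != config$grid_size) {
    stop("community size ", n, " does not match grid_size ", config$grid_size)
  }
  start_life <- switch(trial,
                       pretraining = config$pretraining_start_life,
                       training = config$training_start_life,
                       test = config$training_start_life)
  feedback <- trial != "test"
  forced <- trial == "pretraining"  # minimum-engagement rule
  allow_stop <- trial != "pretraining"
  withr::with_seed(rng_seed, {
    perm <- sample.int(n)
    state <- new_game_state(start_life)
    attacked <- logical(n)
    outcome <- character(n)
    presented <- 0L
    for (i in perm) {
      presented <- presented + 1L
      phen <- phenotype_at(prey, i, treatment)
      attack <- if (forced) TRUE else isTRUE(agent_decide(agent, phen))
      attacked[presented] <- attack
      if (attack) {
        out <- prey$profitability[i]
        outcome[presented] <- out
        if (feedback) {
          state <- apply_outcome(state, out, config)
          agent_learn(agent, phen, out)
        } else {
          state$attacks_made <- state$attacks_made + 1L
        }
      } else {
        outcome[presented] <- "not_attacked"
      }
      if (feedback) {
        if (!state$alive) break
        if (state$attacks_made >= config$max_training_attacks) break
      }
      if (allow_stop && isTRUE(agent_stops(agent, trial))) break
    }
    keep <- perm[seq_len(presented)]
    rec <- prey[keep, , drop = FALSE]
    rec$trial <- trial
    rec$presentation_index <- seq_len(presented)
    rec$attacked <- attacked[seq_len(presented)]
    rec$outcome <- outcome[seq_len(presented)]
    rec$experiment_id <- attr(community, "experiment_id")
    rec$treatment_id <- treatment$treatment_id
    rec$final_life <- state$life
    rownames(rec) <- NULL
    rec
  })
}

#' Run a training trial
#'
#' Prey are presented one at a time in a random permutation of the training
#' community. The agent decides whether to attack each prey; attacks yield
#' immediate feedback (passed to the agent's learning rule) and move the life
#' bar. The trial ends after `max_training_attacks` attacks, when the agent
#' dies, when it signals an early stop, or when all prey have been presented.
#'
#' @param community A training `community_spec`.
#' @param agent An agent created by [make_subject()].
#' @param config A [game_config()].
#' @param rng_seed Integer seed controlling prey order and agent decisions.
#' @return A data frame of attack records, one row per presented prey.
#' @export
run_training_trial <- function(community, agent, config = game_config(),
                               rng_seed = 1L) {
  sim_trial(community, agent, config, rng_seed, "training")
}

#' Run the pretraining trial
#'
#' All prey are bad and the life bar starts low enough that the subject dies
#' after four attacks. Subjects cannot stop sampling early; an agent that
#' would decline to attack is compelled to (the minimum-engagement rule), so
#' every agent experiences the cost of bad prey before the experiments.
#'
#' @inheritParams run_training_trial
#' @return A data frame of attack records.
#' @export
run_pretraining <- function(agent, config = game_config(), rng_seed = 1L) {
  community <- build_pretraining_community(total_size = config$grid_size)
  sim_trial(community, agent, config, rng_seed, "pretraining")
}

#' Run a feedback-free test trial
#'
#' The agent may attack any subset of the test community and stop at any
#' time. Outcomes are recorded for scoring but never passed to the agent, and
#' the agent's learned state is left untouched, so the trial measures the
#' categories formed during training without changing them.
#'
#' @param test_community A test `community_spec` from
#'   [build_test_community()].
#' @inheritParams run_training_trial
#' @return A data frame of attack records.
#' @export
run_test_trial <- function(test_community, agent, config = game_config(),
                           rng_seed = 1L) {
  before <- agent_state(agent)
  rec <- sim_trial(test_community, agent, config, rng_seed, "test")
  if (!identical(before, agent_state(agent))) {
    stop("agent state changed during a test trial (no-feedback contract)")
  }
  rec
}

#' Score of a record set
#'
#' The score shown to subjects: good prey attacked minus bad prey attacked.
#'
#' @param records Attack records from any combination of trials.
#' @return Integer score.
#' @export
score_records <- function(records) {
  sum(records$attacked & records$outcome == "good") -
    sum(records$attacked & records$outcome == "bad")
}
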