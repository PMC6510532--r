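# Synthetic predator agents. Each archetype is an explicit model of one of
# the competing categorization hypotheses: none is a claim about how any
# real predator works. Agents are environments holding learned state;
# `agent_decide` / `agent_learn` / `agent_reset` form the contract the game
# runner uses.
#
# Archetypes:
#  - rw_learner: Rescorla-Wagner compound-cue learner. Both displayed trait
#    values share a prediction; each cue's associative strength moves toward
#    the outcome value by alpha times the shared prediction error. Cue
#    competition makes the more valid cue capture the association (the
#    relative validity effect), so this archetype models the hypothesis that
#    predators always end up using the reliable trait.
#  - key_trait: attends only to the binary key (unreliable) trait, keeping
#    mean-payoff tallies per value; models the hypothesis that predators
#    simplify decisions with a key trait regardless of its validity.
#  - memorizer: rote table of per-phenotype outcome tallies with limited
#    capacity (least-recently-reinforced eviction) and a configurable policy
#    for unknown phenotypes; models memory-constrained identification.
#  - human_like: memorizer that falls back on key-trait tallies when a
#    phenotype is not in memory; the composite used as the default study
#    subject, which reproduces the switch from reliable-trait use in poor
#    communities to key-trait use in rich ones.
#  - random: attacks with probability 0.5; the random-guessing hypothesis.

#' Agent archetype descriptors
#'
#' Constructors for the parameter sets of each agent archetype. Pass the
#' result to [make_subject()] to instantiate an agent.
#'
#' @param alpha Rescorla-Wagner learning rate in (0, 1].
#' @param lambda_good,lambda_bad Reinforcement asymptotes; defaults +1 / -2
#'   mirror the game's payoff ratio.
#' @param temperature Softmax temperature (> 0) converting a valuation in
#'   payoff units into an attack probability via
#'   `plogis(value / temperature)`.
#' @param capacity Maximum number of distinct phenotypes the memorizer
#'   retains.
#' @param fallback Decision policy for phenotypes not in memory:
#'   `"optimistic"` (value +0.5), `"pessimistic"` (-0.5), or `"key_trait"`
#'   (use the key-trait tallies).
#' @param p_attack Attack probability of the random archetype.
#' @return An `agent_archetype` list.
#' @export
archetype_rw <- function(alpha = 0.4, lambda_good = 1, lambda_bad = -2,
                         temperature = 1) {
  stopifnot(alpha > 0, alpha <= 1, temperature > 0)
  new_archetype("rw_learner", list(alpha = alpha, lambda_good = lambda_good,
                                   lambda_bad = lambda_bad,
                                   temperature = temperature))
}

#' @rdname archetype_rw
#' @export
archetype_key_trait <- function(lambda_good = 1, lambda_bad = -2) {
  new_archetype("key_trait", list(lambda_good = lambda_good,
                                  lambda_bad = lambda_bad))
}

#' @rdname archetype_rw
#' @export
archetype_memorizer <- function(capacity = 6L, fallback = "optimistic",
                                lambda_good = 1, lambda_bad = -2,
                                temperature = 1) {
  fallback <- match.arg(fallback, c("optimistic", "pessimistic", "key_trait"))
  stopifnot(capacity >= 1, temperature > 0)
  new_archetype("memorizer", list(capacity = as.integer(capacity),
                                  fallback = fallback,
                                  lambda_good = lambda_good,
                                  lambda_bad = lambda_bad,
                                  temperature = temperature))
}

#' @rdname archetype_rw
#' @export
archetype_human_like <- function(capacity = 6L, lambda_good = 1,
                                 lambda_bad = -2, temperature = 1) {
  a <- archetype_memorizer(capacity, "key_trait", lambda_good, lambda_bad,
                           temperature)
  a$kind <- "human_like"
  a
}

#' @rdname archetype_rw
#' @export
archetype_random <- function(p_attack = 0.5) {
  stopifnot(p_attack >= 0, p_attack <= 1)
  new_archetype("random", list(p_attack = p_attack))
}

new_archetype <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "agent_archetype")
}

resolve_archetype <- function(archetype) {
  if (inherits(archetype, "agent_archetype")) return(archetype)
  if (is.character(archetype) && length(archetype) == 1L) {
    return(switch(archetype,
                  rw_learner = archetype_rw(),
                  key_trait = archetype_key_trait(),
                  memorizer = archetype_memorizer(),
                  human_like = archetype_human_like(),
                  random = archetype_random(),
                  stop("unknown archetype: ", archetype)))
  }
  stop("archetype must be an agent_archetype or a kind name")
}

#' Instantiate a fresh agent
#'
#' @param archetype An `agent_archetype` (see [archetype_rw()] and friends)
#'   or an archetype kind name.
#' @param seed Integer seed stored with the agent; the study runner derives
#'   per-trial RNG streams from it so that identical archetype + seed yields
#'   identical behavior.
#' @return An agent (an environment with class `<kind>_agent` /
#'   `vp_agent`).
#' @export
make_subject <- function(archetype, seed = 1L) {
  archetype <- resolve_archetype(archetype)
  kind <- archetype$kind
  class_kind <- if (kind == "human_like") "memorizer" else kind
  agent <- new.env(parent = emptyenv())
  agent$kind <- kind
  agent$params <- archetype$params
  agent$seed <- as.integer(seed)
  class(agent) <- c(paste0(class_kind, "_agent"), "vp_agent")
  agent_reset(agent)
  agent
}

# ---- generic contract -------------------------------------------------

#' Agent contract generics
#'
#' `agent_decide` returns whether the agent attacks the presented phenotype
#' (may use the RNG stream); `agent_learn` feeds back the outcome of an
#' attack during feedback trials; `agent_reset` clears learned state (called
#' between experiments, mirroring the shuffling of display values that
#' prevents generalization across experiments); `agent_stops` is an optional
#' early-stop signal; `agent_state` returns a snapshot of the learned state
#' used to assert that test trials never change it.
#'
#' @param agent An agent from [make_subject()].
#' @param phenotype A displayed phenotype (list with the display values,
#'   role labels, and trait dimensions).
#' @param outcome `"good"` or `"bad"`.
#' @param trial Trial type string.
#' @name agent-contract
NULL

#' @rdname agent-contract
#' @export
agent_decide <- function(agent, phenotype) UseMethod("agent_decide")

#' @rdname agent-contract
#' @export
agent_learn <- function(agent, phenotype, outcome) UseMethod("agent_learn")

#' @rdname agent-contract
#' @export
agent_reset <- function(agent) UseMethod("agent_reset")

#' @rdname agent-contract
#' @export
agent_stops <- function(agent, trial) UseMethod("agent_stops")

#' @rdname agent-contract
#' @export
agent_state <- function(agent) UseMethod("agent_state")

#' @export
agent_learn.default <- function(agent, phenotype, outcome) invisible(agent)

#' @export
agent_stops.default <- function(agent, trial) FALSE

#' @export
agent_state.default <- function(agent) NULL

payoff_of <- function(outcome, params) {
  if (outcome == "good") params$lambda_good else params$lambda_bad
}

display_cues <- function(phenotype) {
  c(paste0(phenotype$reliable_dim, ":", phenotype$reliable_display),
    paste0(phenotype$unreliable_dim, ":", phenotype$unreliable_display))
}

# ---- Rescorla-Wagner learner ------------------------------------------

#' Rescorla-Wagner update for compound cues
#'
#' All displayed cues share a prediction `sum(V)`; each displayed cue's
#' strength moves toward the outcome asymptote by `alpha` times the shared
#' prediction error: `V_i <- V_i + alpha * (lambda - sum(V))`. Non-displayed
#' cues are unchanged. Cue competition through the shared error term is what
#' produces the relative validity effect.
#'
#' @param state A list with `V` (named numeric of associative strengths),
#'   `alpha`, `lambda_good`, `lambda_bad`.
#' @param cues Character vector of displayed cue identifiers.
#' @param outcome `"good"` or `"bad"`.
#' @return The updated state.
#' @export
rw_update <- function(state, cues, outcome) {
  outcome <- match.arg(outcome, c("good", "bad"))
  lambda <- if (outcome == "good") state$lambda_good else state$lambda_bad
  v <- state$V
  missing <- setdiff(cues, names(v))
  if (length(missing)) v[missing] <- 0
  pred <- sum(v[cues])
  v[cues] <- v[cues] + state$alpha * (lambda - pred)
  state$V <- v
  state
}

rw_prediction <- function(V, cues) {
  sum(V[intersect(cues, names(V))])
}

#' @export
agent_decide.rw_learner_agent <- function(agent, phenotype) {
  pred <- rw_prediction(agent$V, display_cues(phenotype))
  stats::runif(1) < stats::plogis(pred / agent$params$temperature)
}

#' @export
agent_learn.rw_learner_agent <- function(agent, phenotype, outcome) {
  st <- rw_update(list(V = agent$V, alpha = agent$params$alpha,
                       lambda_good = agent$params$lambda_good,
                       lambda_bad = agent$params$lambda_bad),
                  display_cues(phenotype), outcome)
  agent$V <- st$V
  invisible(agent)
}

#' @export
agent_reset.rw_learner_agent <- function(agent) {
  agent$V <- stats::setNames(numeric(0), character(0))
  invisible(agent)
}

#' @export
agent_state.rw_learner_agent <- function(agent) list(V = agent$V)

# ---- key-trait agent ---------------------------------------------------

key_estimate <- function(tally, value) {
  t <- tally[[value]]
  if (is.null(t) || t[["n"]] == 0) return(NA_real_)
  t[["sum"]] / t[["n"]]
}

#' @export
agent_decide.key_trait_agent <- function(agent, phenotype) {
  est <- key_estimate(agent$tally, phenotype$unreliable_value)
  # deterministic once the tallies favor one side; random otherwise
  if (is.na(est) || est == 0) return(stats::runif(1) < 0.5)
  est > 0
}

#' @export
agent_learn.key_trait_agent <- function(agent, phenotype, outcome) {
  v <- phenotype$unreliable_value
  t <- agent$tally[[v]]
  if (is.null(t)) t <- c(n = 0, sum = 0)
  t[["n"]] <- t[["n"]] + 1
  t[["sum"]] <- t[["sum"]] + payoff_of(outcome, agent$params)
  agent$tally[[v]] <- t
  invisible(agent)
}

#' @export
agent_reset.key_trait_agent <- function(agent) {
  agent$tally <- list()
  invisible(agent)
}

#' @export
agent_state.key_trait_agent <- function(agent) list(tally = agent$tally)

# ---- memorizer (and human_like composite) ------------------------------

memory_key <- function(phenotype) {
  paste(phenotype$reliable_display, phenotype$unreliable_display, sep = "|")
}

#' @export
agent_decide.memorizer_agent <- function(agent, phenotype) {
  key <- memory_key(phenotype)
  t <- agent$table[[key]]
  value <- if (!is.null(t)) {
    (t[["good"]] * agent$params$lambda_good +
       t[["bad"]] * agent$params$lambda_bad) / (t[["good"]] + t[["bad"]])
  } else {
    switch(agent$params$fallback,
           optimistic = 0.5,
           pessimistic = -0.5,
           key_trait = {
             est <- key_estimate(agent$utally, phenotype$unreliable_value)
             if (is.na(est)) 0 else est
           })
  }
  stats::runif(1) < stats::plogis(value / agent$params$temperature)
}

#' @export
agent_learn.memorizer_agent <- function(agent, phenotype, outcome) {
  key <- memory_key(phenotype)
  t <- agent$table[[key]]
  if (is.null(t)) t <- c(good = 0, bad = 0)
  t[[outcome]] <- t[[outcome]] + 1
  agent$table[[key]] <- t
  agent$recency <- c(setdiff(agent$recency, key), key)
  if (length(agent$table) > agent$params$capacity) {
    evict <- agent$recency[1L]  # least recently reinforced
    agent$table[[evict]] <- NULL
    agent$recency <- agent$recency[-1L]
  }
  # key-trait tallies back the fallback policy
  v <- phenotype$unreliable_value
  u <- agent$utally[[v]]
  if (is.null(u)) u <- c(n = 0, sum = 0)
  u[["n"]] <- u[["n"]] + 1
  u[["sum"]] <- u[["sum"]] + payoff_of(outcome, agent$params)
  agent$utally[[v]] <- u
  invisible(agent)
}

#' @export
agent_reset.memorizer_agent <- function(agent) {
  agent$table <- list()
  agent$recency <- character(0)
  agent$utally <- list()
  invisible(agent)
}

#' @export
agent_state.memorizer_agent <- function(agent) {
  list(table = agent$table, recency = agent$recency, utally = agent$utally)
}

# ---- random agent ------------------------------------------------------

#' @export
agent_decide.random_agent <- function(agent, phenotype) {
  stats::runif(1) < agent$params$p_attack
}

#' @export
agent_reset.random_agent <- function(agent) invisible(agent)

#' @export
print.vp_agent <- function(x, ...) {
  cat(sprintf("<agent: %s, seed %d>\n", x$kind, x$seed))
  invisible(x)
}
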