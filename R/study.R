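# Study orchestration: subjects x experiments x treatments, randomization
# and balancing, per-subject seed streams, persistence, and the end-to-end
# report.

#' Study configuration
#'
#' @param n_subjects Number of simulated subjects (default 45, the size of
#'   the original volunteer pool).
#' @param archetypes Named list mapping archetype kind (or an
#'   `agent_archetype`) to its proportion of subjects; proportions must sum
#'   to 1. Default: all subjects are the composite `human_like` agent.
#' @param master_seed Integer master seed; all per-subject and per-trial
#'   streams derive from it, so identical configurations reproduce byte-
#'   identical records.
#' @param game A [game_config()].
#' @param balance_treatments If `TRUE` (default) treatments within each
#'   experiment are assigned from a shuffled balanced sequence, so counts
#'   differ by at most one; otherwise they are drawn uniformly.
#' @param total_size Community size passed to the community builders.
#' @param abundances Optional named list of per-experiment abundance
#'   overrides (see [build_training_community()]).
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 45L,
                         archetypes = list(human_like = 1),
                         master_seed = 1L,
                         game = game_config(),
                         balance_treatments = TRUE,
                         total_size = 36L,
                         abundances = NULL) {
  props <- vapply(archetypes, archetype_proportion, 0)
  if (abs(sum(props) - 1) > 1e-8) {
    stop("archetype proportions must sum to 1, got ", sum(props))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 archetypes = archetypes, master_seed = as.integer(master_seed),
                 game = game, balance_treatments = isTRUE(balance_treatments),
                 total_size = as.integer(total_size),
                 abundances = abundances),
            class = "study_config")
}

# Counter-based seed derivation: adding subjects never perturbs the streams
# of earlier ones. Kept below 2^31 - 1; exact in double arithmetic.
derive_seed <- function(master, subject, counter = 0L) {
  as.integer((master * 69069 + subject * 7919 + counter * 104729 + 1) %%
               2147483647)
}

archetype_proportion <- function(x) {
  if (inherits(x, "agent_archetype")) {
    x$proportion %||% 1
  } else if (is.list(x)) {
    x$proportion %||% 1
  } else {
    as.numeric(x)
  }
}

# Largest-remainder apportionment of subjects to archetypes.
apportion_subjects <- function(archetypes, n) {
  props <- vapply(archetypes, archetype_proportion, 0)
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  rep(names(archetypes), counts)
}

#' Run a full in-silico study
#'
#' Each subject completes the pretraining trial once, then the five
#' experiments in an independent random order, taking the feedback-free test
#' trial immediately after each training trial. Treatments are assigned at
#' random within each experiment (balanced so counts differ by at most one,
#' by default). Agent state is reset between experiments, mirroring the
#' shuffling of display values that prevents generalization across
#' experiments; the runner verifies that test trials never change agent
#' state.
#'
#' @param config A [study_config()].
#' @return A `study_result` list: `records` (tidy attack table over all
#'   trials), `subjects` (per-subject metadata), `scores` (per
#'   subject-experiment score), `config`.
#' @export
run_study <- function(config = study_config()) {
  n <- config$n_subjects
  kinds <- apportion_subjects(config$archetypes, n)
  subject_ids <- sprintf("S%03d", seq_len(n))
  # study-level randomization (orders, treatment assignment)
  design <- withr::with_seed(derive_seed(config$master_seed, 0L), {
    orders <- t(vapply(seq_len(n), function(i) sample.int(5L), integer(5)))
    trts <- vapply(1:5, function(e) {
      if (config$balance_treatments) {
        sample(rep_len(1:4, n))
      } else {
        sample.int(4L, n, replace = TRUE)
      }
    }, integer(n))
    list(orders = orders, trts = matrix(trts, nrow = n))
  })
  all_records <- vector("list", n)
  subject_rows <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- kinds[i]
    arch <- config$archetypes[[kind]]
    arch <- if (inherits(arch, "agent_archetype")) arch else
      resolve_archetype(kind)
    sseed <- derive_seed(config$master_seed, i)
    agent <- make_subject(arch, sseed)
    recs <- list(run_pretraining(agent, config$game,
                                 derive_seed(sseed, i, 1L)))
    recs[[1]]$order <- 0L
    for (j in 1:5) {
      e <- design$orders[i, j]
      tm <- treatment_map(e, design$trts[i, e])
      agent_reset(agent)
      training <- build_training_community(
        e, tm, config$total_size,
        abundances = config$abundances[[as.character(e)]]
      )
      tr_rec <- run_training_trial(training, agent, config$game,
                                   derive_seed(sseed, i, 10L + 2L * j))
      test <- build_test_community(tm, config$total_size)
      te_rec <- run_test_trial(test, agent, config$game,
                               derive_seed(sseed, i, 11L + 2L * j))
      tr_rec$order <- j
      te_rec$order <- j
      recs[[length(recs) + 1L]] <- tr_rec
      recs[[length(recs) + 1L]] <- te_rec
    }
    srec <- do.call(rbind, recs)
    srec$subject_id <- subject_ids[i]
    srec$archetype <- kind
    all_records[[i]] <- srec
    subject_rows[[i]] <- data.frame(
      subject_id = subject_ids[i], archetype = kind, seed = sseed,
      order = paste(design$orders[i, ], collapse = ","),
      treatments = paste(design$trts[i, ], collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, all_records)
  records <- records[, c("subject_id", "archetype", "experiment_id",
                         "treatment_id", "trial", "order",
                         "presentation_index", "reliable_value",
                         "reliable_polarity", "reliable_display",
                         "unreliable_value", "unreliable_display",
                         "profitability", "focal", "attacked", "outcome")]
  rownames(records) <- NULL
  expr <- records[records$trial != "pretraining", , drop = FALSE]
  scores <- stats::aggregate(
    cbind(score = as.integer(expr$attacked & expr$outcome == "good") -
            as.integer(expr$attacked & expr$outcome == "bad"))
    ~ subject_id + experiment_id, data = expr, FUN = sum
  )
  structure(list(records = records,
                 subjects = do.call(rbind, subject_rows),
                 scores = scores,
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %d subjects, %d records>\n",
              nrow(x$subjects), nrow(x$records)))
  invisible(x)
}

#' Reproduce the headline report from attack records
#'
#' Runs the full analysis pipeline: the no-intercept logit fit, the
#' per-experiment trait contrasts, the Bonferroni-grouped total
#' discrimination (sum) and relative reliable-trait use (difference) tables,
#' and the split-vs-lumped likelihood-ratio test.
#'
#' @param records Attack records covering at least two experiments.
#' @param communities Optional community metadata for [prepare_table()].
#' @return A list with `contrasts`, `total_discrimination` (grouping of
#'   sums), `relative_reliable_use` (grouping of differences), `lrt`,
#'   `fit`.
#' @export
reproduce_report <- function(records, communities = NULL) {
  tab <- prepare_table(records, communities)
  if (nlevels(droplevels(tab$experiment)) < 2L) {
    stop("records must cover at least 2 experiments")
  }
  fit <- fit_model(tab)
  list(contrasts = trait_contrasts(fit),
       total_discrimination = pairwise_groupings(fit, "sum"),
       relative_reliable_use = pairwise_groupings(fit, "difference"),
       lrt = split_value_lrt(tab),
       fit = fit)
}

#' Write a report to disk
#'
#' @param report A list from [reproduce_report()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$total_discrimination$estimates,
                   file.path(dir, "total_discrimination.csv"),
                   row.names = FALSE)
  utils::write.csv(report$relative_reliable_use$estimates,
                   file.path(dir, "relative_reliable_use.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$lrt, file.path(dir, "lrt.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
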