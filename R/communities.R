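# Prey community construction: the five training communities, the common
# test community, treatment permutations, and diversity statistics.
#
# Phenotypes are symbolic. Each prey carries two discrete traits, one on the
# "shape" dimension and one on the "color" dimension. Within an experiment one
# dimension is the reliable trait R (its values perfectly predict
# profitability) and the other is the binary unreliable trait U (predicts
# profitability with probability 0.78). Reliable values are labelled by role:
# "G1", "G2", ... are associated with good prey, "B1", "B2", ... with bad
# prey; the unreliable values are "U+" (good-associated) and "U-". A
# treatment map assigns concrete display values (circle, blue, ...) to roles.

SHAPE_PALETTE <- c("circle", "cross", "square", "diamond",
                   "star", "triangle", "pentagon", "heart")
COLOR_PALETTE <- c("blue", "yellow", "red", "green",
                   "purple", "orange", "brown", "pink")

# reliable-trait values per profitability class, experiments 1-5
VALUES_PER_CLASS <- c(1L, 2L, 4L, 2L, 4L)

# default abundance of each good reliable value at community size 36 (bad
# values mirror these); chosen to satisfy the stated design constraints:
# 1:1 good:bad, richness 2/4/8/4/8, experiments 2/4 and 3/5 sharing phenotype
# sets, and experiments 4/5 uneven with one dominant value per class
DEFAULT_ABUNDANCES <- list(
  `1` = 18L,
  `2` = c(9L, 9L),
  `3` = c(5L, 5L, 4L, 4L),
  `4` = c(14L, 4L),
  `5` = c(12L, 2L, 2L, 2L)
)

# probability that the unreliable trait value is congruent with profitability
U_VALIDITY <- 0.78

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate the four treatments of an experiment
#'
#' Each experiment is run under four treatments. In two of them shape is the
#' reliable dimension and color the unreliable one; in the other two the
#' dimensions swap. Within the treatments sharing a reliable dimension, the
#' assignment of concrete values to the good/bad roles is permuted so that no
#' concrete value keeps its meaning, preventing generalization across
#' treatments.
#'
#' @param experiment_id Integer 1..5.
#' @return A list of four `treatment_map` objects.
#' @export
enumerate_treatments <- function(experiment_id) {
  lapply(1:4, function(t) treatment_map(experiment_id, t))
}

#' Construct a treatment map
#'
#' A treatment map is a bijection from abstract phenotype roles (G1..Gm,
#' B1..Bm, U+, U-) to concrete display values on the shape and color
#' dimensions. Roles always cover at least two values per class so that the
#' common test community (which uses G1, G2, B1, B2) can be displayed under
#' any experiment's treatments.
#'
#' @param experiment_id Integer 1..5.
#' @param treatment_id Integer 1..4. Treatments 1-2 use shape as the
#'   reliable dimension, treatments 3-4 use color.
#' @return An object of class `treatment_map`.
#' @export
treatment_map <- function(experiment_id, treatment_id) {
  experiment_id <- check_experiment_id(experiment_id)
  if (!treatment_id %in% 1:4) {
    stop("treatment_id must be in 1..4, got ", treatment_id)
  }
  k <- VALUES_PER_CLASS[experiment_id]
  m <- max(k, 2L)  # test community needs two values per class
  reliable_dim <- if (treatment_id <= 2L) "shape" else "color"
  rel_pal <- if (reliable_dim == "shape") SHAPE_PALETTE else COLOR_PALETTE
  unrel_pal <- if (reliable_dim == "shape") COLOR_PALETTE[1:2] else
    SHAPE_PALETTE[c(1L, 5L)]  # circle / star
  roles <- c(paste0("G", seq_len(m)), paste0("B", seq_len(m)))
  flip <- treatment_id %% 2L == 0L
  rel_vals <- if (flip) rel_pal[c((m + 1):(2 * m), 1:m)] else rel_pal[1:(2 * m)]
  u_vals <- if (flip) rev(unrel_pal) else unrel_pal
  assignment <- c(stats::setNames(rel_vals, roles),
                  stats::setNames(u_vals, c("U+", "U-")))
  structure(
    list(experiment_id = experiment_id, treatment_id = as.integer(treatment_id),
         reliable_dim = reliable_dim,
         unreliable_dim = if (reliable_dim == "shape") "color" else "shape",
         assignment = assignment),
    class = "treatment_map"
  )
}

check_experiment_id <- function(experiment_id) {
  if (length(experiment_id) != 1L || !experiment_id %in% 1:5) {
    stop("unknown experiment_id: ", paste(experiment_id, collapse = ","),
         " (must be 1..5)")
  }
  as.integer(experiment_id)
}

# Split a per-class congruent count across reliable values proportionally to
# abundance; remainders go to the most abundant values first (ties broken by
# lowest value index), skipping values whose incongruent cell would be
# emptied so that every (value, U) phenotype present keeps nonzero abundance
# whenever possible.
allocate_congruent <- function(abundance, n_congruent) {
  base <- floor(n_congruent * abundance / sum(abundance))
  rem <- n_congruent - sum(base)
  ord <- order(-abundance, seq_along(abundance))
  for (pass in 1:2) {
    for (i in ord) {
      if (rem == 0L) break
      room <- abundance[i] - base[i]
      keep_one <- if (pass == 1L) 1L else 0L
      if (room - keep_one >= 1L) {
        base[i] <- base[i] + 1L
        rem <- rem - 1L
      }
    }
    if (rem == 0L) break
  }
  if (rem != 0L) stop("cannot allocate congruent prey across values")
  as.integer(base)
}

congruent_per_class <- function(total_size) {
  per_class <- round(U_VALIDITY * total_size / 2)
  if (abs(2 * per_class - U_VALIDITY * total_size) > 1) {
    stop("total_size ", total_size, " cannot realize the ", U_VALIDITY,
         " unreliable-trait validity within one prey")
  }
  as.integer(per_class)
}

# Build phenotype rows for one profitability class.
class_rows <- function(values, abundance, congruent, profitability) {
  u_cong <- if (profitability == "good") "U+" else "U-"
  u_inc <- if (profitability == "good") "U-" else "U+"
  rows <- list()
  for (i in seq_along(values)) {
    rows[[length(rows) + 1L]] <- data.frame(
      reliable_value = values[i],
      reliable_polarity = if (profitability == "good") "+" else "-",
      profitability = profitability,
      unreliable_value = u_cong,
      abundance = congruent[i],
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      reliable_value = values[i],
      reliable_polarity = if (profitability == "good") "+" else "-",
      profitability = profitability,
      unreliable_value = u_inc,
      abundance = abundance[i] - congruent[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out[out$abundance > 0L, , drop = FALSE]
}

finish_community <- function(rows, experiment_id, treatment, total_size, type) {
  rows$reliable_display <-
    unname(treatment$assignment[rows$reliable_value])
  rows$unreliable_display <-
    unname(treatment$assignment[rows$unreliable_value])
  rows$congruent <- (rows$profitability == "good" &
                       rows$unreliable_value == "U+") |
    (rows$profitability == "bad" & rows$unreliable_value == "U-")
  # focal prey: the four most abundant phenotypes; ties prefer the congruent
  # pairing, then the lowest value index
  idx <- as.integer(sub("^[GB]", "", rows$reliable_value))
  ord <- order(-rows$abundance, !rows$congruent, idx, rows$reliable_polarity)
  rows$focal <- FALSE
  rows$focal[ord[seq_len(min(4L, nrow(rows)))]] <- TRUE
  rows$experiment_id <- experiment_id
  rows$treatment_id <- treatment$treatment_id
  rownames(rows) <- NULL
  structure(rows,
            class = c("community_spec", "data.frame"),
            experiment_id = experiment_id,
            treatment = treatment,
            total_size = total_size,
            type = type)
}

#' Build a training community
#'
#' Constructs the prey community used in the training trial of one
#' experiment under one treatment: `total_size` prey, a 1:1 ratio of good to
#' bad prey, reliable-trait richness 2/4/8/4/8 for experiments 1-5, and a
#' fraction of prey (0.78 at the default size: 28 of 36) whose binary
#' unreliable-trait value is congruent with their profitability.
#' Experiments 4 and 5 are uneven versions of experiments 2 and 3: the same
#' phenotypes, but one good and one bad reliable value dominate.
#'
#' @param experiment_id Integer 1..5.
#' @param treatment A `treatment_map` (default: treatment 1 of the
#'   experiment).
#' @param total_size Number of prey; must be divisible by 4 (default 36).
#' @param abundances Optional override of the per-good-value abundance
#'   vector (bad values mirror it); must sum to `total_size / 2`.
#' @return A `community_spec`: a data frame with one row per phenotype
#'   (reliable value x unreliable value) and its abundance, with the focal
#'   phenotypes flagged.
#' @export
build_training_community <- function(experiment_id, treatment = NULL,
                                     total_size = 36L, abundances = NULL) {
  experiment_id <- check_experiment_id(experiment_id)
  treatment <- treatment %||% treatment_map(experiment_id, 1L)
  if (treatment$experiment_id != experiment_id) {
    stop("treatment map is for experiment ", treatment$experiment_id,
         ", not ", experiment_id)
  }
  if (total_size %% 4L != 0L) {
    stop("total_size must be divisible by 4, got ", total_size)
  }
  ab <- abundances %||% {
    scale <- total_size / 36
    scaled <- DEFAULT_ABUNDANCES[[as.character(experiment_id)]] * scale
    if (any(scaled != round(scaled))) {
      stop("default abundances do not scale to total_size ", total_size,
           "; pass `abundances` explicitly")
    }
    as.integer(scaled)
  }
  if (sum(ab) != total_size / 2L) {
    stop("abundances must sum to total_size / 2 = ", total_size / 2L)
  }
  k <- length(ab)
  per_class <- congruent_per_class(total_size)
  cong <- allocate_congruent(ab, per_class)
  rows <- rbind(
    class_rows(paste0("G", seq_len(k)), ab, cong, "good"),
    class_rows(paste0("B", seq_len(k)), ab, cong, "bad")
  )
  finish_community(rows, experiment_id, treatment, total_size, "training")
}

#' Build the common test community
#'
#' The test trial community is identical for every experiment and treatment
#' (up to the treatment's assignment of display values): four reliable-trait
#' values (G1, G2 good; B1, B2 bad), each crossed with both unreliable
#' values, with the same 1:1 profitability ratio and 0.78 congruence
#' structure as the training communities.
#'
#' @param treatment A `treatment_map`.
#' @param total_size Number of prey, divisible by 4 (default 36).
#' @return A `community_spec`.
#' @export
build_test_community <- function(treatment, total_size = 36L) {
  if (!inherits(treatment, "treatment_map")) {
    stop("treatment must be a treatment_map")
  }
  if (total_size %% 4L != 0L) {
    stop("total_size must be divisible by 4, got ", total_size)
  }
  ab <- rep(total_size %/% 4L, 2L)
  per_class <- congruent_per_class(total_size)
  cong <- allocate_congruent(ab, per_class)
  rows <- rbind(
    class_rows(c("G1", "G2"), ab, cong, "good"),
    class_rows(c("B1", "B2"), ab, cong, "bad")
  )
  finish_community(rows, treatment$experiment_id, treatment, total_size,
                   "test")
}

# Community used in the single pretraining trial: all prey bad, one dedicated
# phenotype whose display values appear in no experimental palette slot used
# for training, so pretraining experience cannot transfer.
build_pretraining_community <- function(treatment = NULL, total_size = 36L) {
  treatment <- treatment %||% treatment_map(1L, 1L)
  rows <- data.frame(
    reliable_value = "P1", reliable_polarity = "-", profitability = "bad",
    unreliable_value = "U-", abundance = as.integer(total_size),
    stringsAsFactors = FALSE
  )
  rows$reliable_display <- "blob"
  rows$unreliable_display <- "gray"
  rows$congruent <- TRUE
  rows$focal <- FALSE
  rows$experiment_id <- 0L
  rows$treatment_id <- treatment$treatment_id
  structure(rows,
            class = c("community_spec", "data.frame"),
            experiment_id = 0L, treatment = treatment,
            total_size = total_size, type = "pretraining")
}

#' Diversity statistics of a community
#'
#' Richness is the number of distinct reliable-trait values; effective
#' richness is the Hill number of order 1, `exp(H)` where `H` is the Shannon
#' entropy of the reliable-value abundance distribution; evenness is
#' effective richness divided by richness, so it is 1 exactly when
#' abundances are uniform.
#'
#' @param spec A `community_spec`.
#' @return A list with elements `richness`, `effective_richness`, `evenness`.
#' @export
diversity_stats <- function(spec) {
  if (!inherits(spec, "community_spec") || nrow(spec) == 0L) {
    stop("spec must be a non-empty community_spec")
  }
  ab <- tapply(spec$abundance, spec$reliable_value, sum)
  p <- ab / sum(ab)
  h <- -sum(p * log(p))
  richness <- length(ab)
  eff <- exp(h)
  list(richness = as.integer(richness),
       effective_richness = eff,
       evenness = eff / richness)
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("<community_spec: %s, experiment %d, treatment %d, %d prey>\n",
              attr(x, "type"), attr(x, "experiment_id"),
              attr(x, "treatment")$treatment_id, sum(x$abundance)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Serialize communities to a long-format CSV
#'
#' @param specs A `community_spec` or list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_communities_csv <- function(specs, path) {
  if (inherits(specs, "community_spec")) specs <- list(specs)
  rows <- do.call(rbind, lapply(specs, function(s) {
    data.frame(
      experiment = attr(s, "experiment_id"),
      treatment = attr(s, "treatment")$treatment_id,
      type = attr(s, "type"),
      reliable_value = s$reliable_value,
      reliable_polarity = s$reliable_polarity,
      unreliable_value = s$unreliable_value,
      profitability = s$profitability,
      reliable_display = s$reliable_display,
      unreliable_display = s$unreliable_display,
      abundance = s$abundance,
      focal = s$focal,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a community to YAML (and back)
#'
#' @param spec A `community_spec`.
#' @param path Output file path.
#' @return `community_to_yaml`: the path, invisibly. `community_from_yaml`:
#'   a `community_spec`.
#' @export
community_to_yaml <- function(spec, path) {
  payload <- list(
    experiment_id = attr(spec, "experiment_id"),
    treatment_id = attr(spec, "treatment")$treatment_id,
    total_size = attr(spec, "total_size"),
    type = attr(spec, "type"),
    phenotypes = lapply(seq_len(nrow(spec)), function(i) as.list(spec[i, ]))
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname community_to_yaml
#' @export
community_from_yaml <- function(path) {
  payload <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(payload$phenotypes, function(p) {
    as.data.frame(p, stringsAsFactors = FALSE)
  }))
  tm <- treatment_map(max(1L, payload$experiment_id), payload$treatment_id)
  structure(rows,
            class = c("community_spec", "data.frame"),
            experiment_id = payload$experiment_id,
            treatment = tm,
            total_size = payload$total_size,
            type = payload$type)
}

# Reliable values present in an experiment's training community and the
# focal values analysed across experiments; role labels do not depend on the
# treatment, so treatment 1 is representative.
training_value_set <- function(experiment_id) {
  k <- VALUES_PER_CLASS[check_experiment_id(experiment_id)]
  c(paste0("G", seq_len(k)), paste0("B", seq_len(k)))
}

focal_value_set <- function(experiment_id) {
  spec <- build_training_community(experiment_id)
  sort(unique(spec$reliable_value[spec$focal]))
}
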