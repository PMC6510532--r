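# Statistical pipeline for test-trial attack records: focal-prey recoding,
# the no-intercept binomial-logit model, delta-method contrasts within and
# between experiments with Bonferroni-grouped pairwise comparisons, total
# discrimination sums, and the split-vs-lumped likelihood-ratio test.

#' Prepare the analysis table from attack records
#'
#' Keeps test-trial records of focal prey. Focal prey are the four most
#' abundant phenotypes of an experiment's training community; because the
#' unreliable value of the four most abundant phenotypes is confounded with
#' profitability, the analysis retains every test prey whose *reliable value*
#' belongs to a focal phenotype, so that both traits vary independently
#' among the analysed rows. Reliable values present in the test community
#' but absent from an experiment's training community are eliminated (this
#' affects only experiment 1, whose training community has two reliable
#' values). Reliable values are recoded by their training association
#' ("G"/"B") and both traits plus the presentation-order covariate are
#' centered (coded 0/1 then reduced by the column mean), so that lower-order
#' terms are interpreted at the mean of the interacting variables.
#'
#' @param records Attack records (data frame from [run_study()] or
#'   [read_records()]); must contain test trials.
#' @param communities Optional named list mapping experiment id to its
#'   training `community_spec` (used to derive focal and training value
#'   sets); defaults to the package's standard designs.
#' @return An `analysis_table` data frame with columns `attacked`,
#'   `experiment`, `subject`, `reliable_value`, `R`, `U`, `R_c`, `U_c`,
#'   `order_c`.
#' @export
prepare_table <- function(records, communities = NULL) {
  needed <- c("subject_id", "experiment_id", "trial", "order",
              "reliable_value", "reliable_polarity", "unreliable_value",
              "attacked")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  }
  tab <- records[records$trial == "test", , drop = FALSE]
  if (nrow(tab) == 0L) stop("records contain no test trials")
  keep <- logical(nrow(tab))
  for (e in unique(tab$experiment_id)) {
    spec <- if (!is.null(communities)) communities[[as.character(e)]] else NULL
    fvals <- if (!is.null(spec)) {
      sort(unique(spec$reliable_value[spec$focal]))
    } else {
      focal_value_set(e)
    }
    tvals <- if (!is.null(spec)) unique(spec$reliable_value) else
      training_value_set(e)
    rows <- tab$experiment_id == e
    keep[rows] <- tab$reliable_value[rows] %in% intersect(fvals, tvals)
  }
  tab <- tab[keep, , drop = FALSE]
  out <- data.frame(
    attacked = as.integer(tab$attacked),
    experiment = factor(tab$experiment_id),
    subject = factor(tab$subject_id),
    reliable_value = tab$reliable_value,
    R = as.integer(tab$reliable_polarity == "+"),
    U = as.integer(tab$unreliable_value == "U+"),
    order = as.numeric(tab$order),
    stringsAsFactors = FALSE
  )
  out$R_c <- out$R - mean(out$R)
  out$U_c <- out$U - mean(out$U)
  out$order_c <- out$order - mean(out$order)
  structure(out, class = c("analysis_table", "data.frame"))
}

#' Fit the no-intercept binomial-logit model
#'
#' Fits, with a logit link,
#' `attacked ~ 0 + experiment + subject + experiment:U_c + experiment:R_c +
#' experiment:U_c:order_c + experiment:R_c:order_c`.
#' There is no intercept and no trait main effect: a deliberate violation of
#' the principle of marginality that makes the per-experiment trait
#' interaction coefficients directly the effects of interest. Subject enters
#' as a fixed main effect to control between-individual variation (the
#' random-effect version of this model does not converge on the original
#' data).
#'
#' @param table An `analysis_table` from [prepare_table()].
#' @param include_subject,include_order,include_experiment Logical switches
#'   that drop the corresponding terms; used for reduced fits on toy data
#'   and diagnostics, not for the study analysis.
#' @param split_reliable If `TRUE`, replace the recoded binary reliable
#'   trait with the original focal reliable values (factor), giving up to
#'   two good and two bad values per experiment; used by
#'   [split_value_lrt()].
#' @return A `fit_result`: coefficients (aliased ones dropped), covariance
#'   matrix, log-likelihood, parameter count, per-experiment term index,
#'   convergence and separation flags.
#' @export
fit_model <- function(table, include_subject = TRUE, include_order = TRUE,
                      include_experiment = TRUE, split_reliable = FALSE) {
  if (nrow(table) == 0L) stop("empty analysis table")
  if (include_subject && nlevels(droplevels(table$subject)) < 2L) {
    stop("the model needs at least 2 subjects (subject is a fixed effect)")
  }
  tab <- table
  tab$experiment <- droplevels(tab$experiment)
  tab$subject <- droplevels(tab$subject)
  rel <- if (split_reliable) "Rv" else "R_c"
  if (split_reliable) tab$Rv <- factor(tab$reliable_value)
  # with a single experiment the experiment factor cannot enter the design;
  # subject dummies (or the trait columns alone) absorb its role
  if (include_experiment && nlevels(tab$experiment) == 1L) {
    include_experiment <- FALSE
  }
  if (include_experiment) {
    terms <- c("experiment",
               if (include_subject) "subject",
               "experiment:U_c", paste0("experiment:", rel),
               if (include_order)
                 c("experiment:U_c:order_c",
                   paste0("experiment:", rel, ":order_c")))
  } else {
    terms <- c("U_c", rel,
               if (include_subject) "subject",
               if (include_order) c("U_c:order_c", paste0(rel, ":order_c")))
  }
  f <- stats::reformulate(terms, response = "attacked", intercept = FALSE)
  fit <- suppressWarnings(
    stats::glm(f, family = stats::binomial(), data = tab)
  )
  beta_all <- stats::coef(fit)
  keep <- !is.na(beta_all)
  beta <- beta_all[keep]
  cov <- stats::vcov(fit)  # aliased coefficients already excluded
  ll <- as.numeric(stats::logLik(fit))
  term_index <- if (!split_reliable) {
    find <- function(trait) {
      if (include_experiment) {
        levs <- levels(tab$experiment)
        nm <- paste0("experiment", levs, ":", trait)
      } else {
        levs <- levels(tab$experiment)[1L]
        nm <- trait
      }
      stats::setNames(nm, levs)[nm %in% names(beta)]
    }
    list(R = find("R_c"), U = find("U_c"))
  } else {
    NULL
  }
  trait_cols <- grep(":(R_c|U_c|Rv)", names(beta), value = TRUE)
  separation <- length(trait_cols) > 0 &&
    any(abs(beta[trait_cols]) > 15)
  structure(
    list(beta = beta, cov = cov, loglik = ll, npar = sum(keep),
         term_index = term_index, converged = isTRUE(fit$converged),
         separation = separation, formula = f,
         n = nrow(tab)),
    class = "fit_result"
  )
}

#' Assemble a fit result from coefficients
#'
#' Constructor for programmatic use (e.g. computing contrasts from published
#' coefficient values without refitting).
#'
#' @param beta Named coefficient vector on the log-odds scale.
#' @param cov Coefficient covariance matrix (defaults to zero).
#' @param term_index List with named character vectors `R` and `U` mapping
#'   experiment labels to coefficient names.
#' @param loglik Optional log-likelihood.
#' @return A `fit_result`.
#' @export
fit_result <- function(beta, cov = NULL, term_index = NULL, loglik = NA_real_) {
  if (is.null(cov)) {
    cov <- matrix(0, length(beta), length(beta),
                  dimnames = list(names(beta), names(beta)))
  }
  stopifnot(nrow(cov) == length(beta), ncol(cov) == length(beta))
  if (max(abs(cov - t(cov))) > 1e-8) stop("cov must be symmetric")
  structure(list(beta = beta, cov = cov, loglik = loglik,
                 npar = length(beta), term_index = term_index,
                 converged = TRUE, separation = FALSE, formula = NULL,
                 n = NA_integer_),
            class = "fit_result")
}

#' Delta-method estimate of a linear contrast
#'
#' For a linear function `c'beta` of the coefficients the delta method is
#' exact: the standard error is `sqrt(c' Sigma c)`. Confidence limits are
#' Wald (normal) intervals and the odds ratio is `exp(estimate)`.
#'
#' @param fit A `fit_result`.
#' @param weights Named numeric vector of contrast weights over coefficient
#'   names (unnamed coefficients get weight 0).
#' @param level Confidence level (default 0.95).
#' @param label Optional label.
#' @return A `contrast_result` list with `estimate`, `se`, `ci`,
#'   `odds_ratio`.
#' @export
delta_contrast <- function(fit, weights, level = 0.95, label = NULL) {
  missing <- setdiff(names(weights), names(fit$beta))
  if (length(missing)) {
    stop("contrast names a term absent from the fit: ",
         paste(missing, collapse = ", "))
  }
  cvec <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  cvec[names(weights)] <- weights
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$cov %*% cvec))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(label = label, estimate = est, se = se,
                 ci = c(est - z * se, est + z * se),
                 odds_ratio = exp(est), level = level),
            class = "contrast_result")
}

#' Per-experiment trait contrasts
#'
#' For each experiment reports the reliable-trait effect, the
#' unreliable-trait effect, their difference (the relative use of the
#' reliable trait: `beta_R - beta_U`, whose exponential is the relative
#' odds of attack due to the reliable versus unreliable trait), and their
#' sum (the total discrimination). Standard errors come from the delta
#' method, which is exact for these linear functions.
#'
#' @param fit A `fit_result` with a term index (from [fit_model()] or
#'   [fit_result()]).
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `experiment`, `effect`, `estimate`,
#'   `se`, `ci_lo`, `ci_hi`, `odds_ratio`.
#' @export
trait_contrasts <- function(fit, level = 0.95) {
  if (is.null(fit$term_index)) stop("fit has no R/U term index")
  exps <- intersect(names(fit$term_index$R), names(fit$term_index$U))
  rows <- list()
  for (e in exps) {
    rn <- fit$term_index$R[[e]]
    un <- fit$term_index$U[[e]]
    specs <- list(
      reliable = stats::setNames(1, rn),
      unreliable = stats::setNames(1, un),
      difference = stats::setNames(c(1, -1), c(rn, un)),
      sum = stats::setNames(c(1, 1), c(rn, un))
    )
    for (eff in names(specs)) {
      ct <- delta_contrast(fit, specs[[eff]], level = level,
                           label = paste0(eff, ".", e))
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = e, effect = eff, estimate = ct$estimate, se = ct$se,
        ci_lo = ct$ci[1], ci_hi = ct$ci[2], odds_ratio = ct$odds_ratio,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# contrast weight vector for one experiment's difference or sum
effect_weights <- function(fit, e, effect) {
  rn <- fit$term_index$R[[e]]
  un <- fit$term_index$U[[e]]
  if (effect == "difference") {
    stats::setNames(c(1, -1), c(rn, un))
  } else if (effect == "sum") {
    stats::setNames(c(1, 1), c(rn, un))
  } else {
    stats::setNames(1, if (effect == "reliable") rn else un)
  }
}

#' Pairwise comparisons between experiments with Bonferroni grouping
#'
#' Computes the chosen per-experiment effect (difference of trait effects by
#' default, or their sum), then all pairwise differences-of-differences
#' between experiments with delta-method standard errors. Confidence
#' intervals are Bonferroni-adjusted for the number of pairwise comparisons
#' (10 for five experiments): a pair differs significantly when its adjusted
#' interval excludes zero. Experiments are then grouped by a compact letter
#' display (insert-and-absorb): two experiments share a letter exactly when
#' their pairwise interval includes zero.
#'
#' @param fit A `fit_result` covering at least two experiments.
#' @param effect `"difference"` or `"sum"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A `grouping_result` list: `estimates` (per-experiment estimate,
#'   se, unadjusted CI, letter group), `pairwise` (all comparisons with
#'   Bonferroni-adjusted CIs), `alpha`, `n_comparisons`.
#' @export
pairwise_groupings <- function(fit, effect = c("difference", "sum"),
                               alpha = 0.05) {
  effect <- match.arg(effect)
  exps <- intersect(names(fit$term_index$R), names(fit$term_index$U))
  k <- length(exps)
  if (k < 2L) stop("need at least 2 experiments for pairwise comparisons")
  ests <- ses <- stats::setNames(numeric(k), exps)
  wlist <- list()
  for (e in exps) {
    w <- effect_weights(fit, e, effect)
    ct <- delta_contrast(fit, w)
    ests[e] <- ct$estimate
    ses[e] <- ct$se
    wlist[[e]] <- w
  }
  pairs <- utils::combn(exps, 2L)
  n_comp <- ncol(pairs)
  z_adj <- stats::qnorm(1 - alpha / (2 * n_comp))
  prows <- list()
  sig <- matrix(FALSE, k, k, dimnames = list(exps, exps))
  for (j in seq_len(n_comp)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    w <- wlist[[a]]
    wb <- wlist[[b]]
    dw <- c(w, -wb)
    # merge weights on shared names
    dw <- tapply(dw, names(dw), sum)
    ct <- delta_contrast(fit, stats::setNames(as.numeric(dw), names(dw)))
    lo <- ct$estimate - z_adj * ct$se
    hi <- ct$estimate + z_adj * ct$se
    s <- lo > 0 || hi < 0
    sig[a, b] <- sig[b, a] <- s
    prows[[j]] <- data.frame(
      experiment_a = a, experiment_b = b, estimate = ct$estimate,
      se = ct$se, ci_lo = lo, ci_hi = hi, significant = s,
      stringsAsFactors = FALSE
    )
  }
  z95 <- stats::qnorm(0.975)
  letters_vec <- cld_insert_absorb(sig, order(-ests))
  estimates <- data.frame(
    experiment = exps, estimate = unname(ests), se = unname(ses),
    ci_lo = unname(ests - z95 * ses), ci_hi = unname(ests + z95 * ses),
    group = letters_vec, stringsAsFactors = FALSE
  )
  structure(list(effect = effect, estimates = estimates,
                 pairwise = do.call(rbind, prows), alpha = alpha,
                 n_comparisons = n_comp),
            class = "grouping_result")
}

# Compact letter display by the insert-and-absorb procedure. `sig` is a
# symmetric logical matrix of significant pairs; `ord` orders items (by
# estimate) for letter assignment.
cld_insert_absorb <- function(sig, ord) {
  items <- rownames(sig)
  k <- length(items)
  cols <- list(rep(TRUE, k))  # each column: logical membership over items
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      # absorb: drop columns that are subsets of another
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && !drop[b] &&
              all(cols[[a]] >= cols[[b]]) && any(cols[[a]] > cols[[b]])) {
            drop[b] <- TRUE
          }
        }
      }
      # dedupe identical columns
      sig_str <- vapply(cols, function(c) paste(as.integer(c), collapse = ""),
                        "")
      drop <- drop | duplicated(sig_str)
      cols <- cols[!drop]
    }
  }
  # assign letters in the order columns first touch the ranked items
  first_rank <- vapply(cols, function(col) min(match(which(col), ord)), 0)
  cols <- cols[order(first_rank)]
  out <- stats::setNames(rep("", k), items)
  for (ci in seq_along(cols)) {
    lab <- letters[ci]
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], lab)
  }
  unname(out)
}

#' Likelihood-ratio test: split versus lumped reliable values
#'
#' Compares the standard model, in which the reliable trait is the recoded
#' binary good/bad factor, against a model that keeps the original focal
#' reliable values (up to two good and two bad per experiment). A
#' significant improvement means predators treated different good (or bad)
#' values differently -- the signature of focusing on the most abundant good
#' value in uneven communities. Both models violate marginality identically,
#' which does not affect the comparison of fit. Degrees of freedom are
#' computed structurally as the difference in estimable parameter counts.
#'
#' @param table_or_records An `analysis_table`, or raw records (prepared
#'   internally).
#' @param communities Passed to [prepare_table()] when records are given.
#' @return A list with `chi2`, `df`, `p`, `loglik_lumped`, `loglik_split`.
#' @export
split_value_lrt <- function(table_or_records, communities = NULL) {
  tab <- if (inherits(table_or_records, "analysis_table")) {
    table_or_records
  } else {
    prepare_table(table_or_records, communities)
  }
  lumped <- fit_model(tab)
  split <- fit_model(tab, split_reliable = TRUE)
  if (split$loglik < lumped$loglik - 1e-6) {
    stop("split model fits worse than lumped: models are not nested")
  }
  chi2 <- 2 * (split$loglik - lumped$loglik)
  df <- split$npar - lumped$npar
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       loglik_lumped = lumped$loglik, loglik_split = split$loglik)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %d coefficients, logLik %.2f, %s%s>\n",
              x$npar, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) ", possible separation" else ""))
  invisible(x)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (se %.3f), %g%% CI [%.3f, %.3f], OR %.3g\n",
              x$label %||% "contrast", x$estimate, x$se, 100 * x$level,
              x$ci[1], x$ci[2], x$odds_ratio))
  invisible(x)
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("<grouping_result: %s, %d pairwise comparisons, alpha %.3f>\n",
              x$effect, x$n_comparisons, x$alpha))
  print(x$estimates, ...)
  invisible(x)
}
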