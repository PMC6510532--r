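test_that("prepare_table recodes, filters and centers", {
  recs <- sim_records(archetype_rw(), experiments = c(1, 2), nsub = 3,
                      seed0 = 2)
  tab <- prepare_table(recs)
  # only test trials, only focal reliable values seen in training
  expect_setequal(unique(tab$reliable_value[tab$experiment == "1"]),
                  c("G1", "B1"))
  expect_setequal(unique(tab$reliable_value[tab$experiment == "2"]),
                  c("G1", "G2", "B1", "B2"))
  # good-associated values recode to R = 1
  expect_true(all(tab$R[grepl("^G", tab$reliable_value)] == 1))
  expect_true(all(tab$R[grepl("^B", tab$reliable_value)] == 0))
  # centering identities
  expect_equal(mean(tab$R_c), 0, tolerance = 1e-12)
  expect_equal(mean(tab$U_c), 0, tolerance = 1e-12)
  expect_equal(mean(tab$order_c), 0, tolerance = 1e-12)
  expect_error(prepare_table(recs[recs$trial != "test", ]), "no test trials")
  expect_error(prepare_table(recs[, -1]), "required columns")
})

test_that("fit_model maximizes the likelihood (gradient and grid oracles)", {
  # gradient of the log-likelihood vanishes at the fit
  recs <- sim_records(archetype_human_like(), experiments = 1:3, nsub = 5,
                      seed0 = 7)
  tab <- prepare_table(recs)
  fit <- fit_model(tab)
  X <- model.matrix(fit$formula, cbind(tab, Rv = factor(tab$reliable_value)))
  X <- X[, names(fit$beta), drop = FALSE]
  p <- plogis(drop(X %*% fit$beta))
  grad <- drop(t(X) %*% (tab$attacked - p))
  expect_lt(max(abs(grad)), 1e-6)
  expect_true(fit$converged)

  # two-parameter toy: traits only, single experiment, against a dense
  # iterative grid search over the likelihood surface
  toy <- withr::with_seed(31, {
    d <- design_table(nsub = 2, experiments = 2)
    d$attacked <- rbinom(nrow(d), 1, plogis(1.2 * d$R_c - 0.4 * d$U_c))
    d
  })
  fit2 <- fit_model(toy, include_subject = FALSE, include_order = FALSE)
  expect_length(fit2$beta, 2L)
  oracle <- grid_logit_2par(toy$attacked, toy$U_c, toy$R_c)
  expect_equal(unname(fit2$beta[c("U_c", "R_c")]), oracle, tolerance = 1e-4)
})

test_that("null data leave each trait coefficient within 2 SE of zero in at
           least 90% of replicates", {
  d <- design_table(nsub = 4, experiments = 2)
  zs <- withr::with_seed(55, {
    vapply(1:200, function(i) {
      d$attacked <- rbinom(nrow(d), 1, 0.5)
      fit <- fit_model(d, include_order = FALSE)
      nm <- c(fit$term_index$R, fit$term_index$U)
      abs(fit$beta[nm]) / sqrt(diag(fit$cov)[nm])
    }, numeric(2))
  })
  expect_gte(mean(zs[1, ] < 2), 0.9)  # reliable-trait coefficient
  expect_gte(mean(zs[2, ] < 2), 0.9)  # unreliable-trait coefficient
})

test_that("trait_contrasts reproduces the worked odds-ratio example", {
  beta <- c(`experiment1:R_c` = 3.36, `experiment1:U_c` = 0.24)
  fit <- fit_result(beta, diag(2e-4, 2),
                    term_index = list(R = c(`1` = "experiment1:R_c"),
                                      U = c(`1` = "experiment1:U_c")))
  ct <- trait_contrasts(fit)
  get <- function(eff, col) ct[ct$effect == eff, col]
  expect_equal(signif(get("reliable", "odds_ratio"), 3), 28.8)
  expect_equal(signif(get("unreliable", "odds_ratio"), 3), 1.27)
  expect_equal(get("difference", "estimate"), 3.12)
  expect_equal(signif(get("difference", "odds_ratio"), 3), 22.6)
  expect_equal(get("sum", "estimate"), 3.6)
})

test_that("delta-method SEs are exact for linear contrasts", {
  # closed form: identity covariance, c = (1, -1) gives sqrt(2)
  fit <- fit_result(c(a = 0.7, b = -0.3), diag(2))
  ct <- delta_contrast(fit, c(a = 1, b = -1))
  expect_equal(ct$se, sqrt(2), tolerance = 1e-15)
  expect_equal(ct$odds_ratio, exp(ct$estimate), tolerance = 1e-15)
  expect_error(delta_contrast(fit, c(zz = 1)), "absent")

  # reparameterization oracle: refitting with a transformed design whose
  # coefficient IS the difference must reproduce the delta-method SE
  recs <- sim_records(archetype_human_like(), experiments = 1:2, nsub = 4,
                      seed0 = 3)
  tab <- prepare_table(recs)
  f <- fit_model(tab, include_order = FALSE)
  for (e in c("1", "2")) {
    rn <- f$term_index$R[[e]]
    un <- f$term_index$U[[e]]
    delta_se <- delta_contrast(f, setNames(c(1, -1), c(rn, un)))$se
    X <- model.matrix(f$formula, tab)[, names(f$beta), drop = FALSE]
    X2 <- X
    X2[, un] <- X[, un] + X[, rn]  # coef of rn becomes beta_R - beta_U
    refit <- glm.fit(X2, tab$attacked, family = binomial())
    se2 <- sqrt(diag(chol2inv(chol(
      t(X2) %*% (X2 * refit$weights)))))[which(colnames(X2) == rn)]
    expect_equal(delta_se, unname(se2), tolerance = 1e-6)
  }
})

test_that("odds ratios equal exp(estimate) to machine precision", {
  recs <- sim_records(archetype_rw(), experiments = 1:2, nsub = 3, seed0 = 9)
  ct <- trait_contrasts(fit_model(prepare_table(recs), include_order = FALSE))
  expect_equal(ct$odds_ratio, exp(ct$estimate), tolerance = 1e-12)
})

test_that("estimates are invariant to which dimension displays the
           reliable trait", {
  recs <- sim_records(archetype_human_like(), experiments = 1:2, nsub = 4,
                      seed0 = 17)
  swapped <- recs
  swapped[c("reliable_display", "unreliable_display")] <-
    recs[c("unreliable_display", "reliable_display")]
  f1 <- fit_model(prepare_table(recs))
  f2 <- fit_model(prepare_table(swapped))
  expect_equal(f1$beta, f2$beta)
})

test_that("pairwise groupings form correct letter displays", {
  mk_fit <- function(ests, se = 0.01) {
    k <- length(ests)
    beta <- se_names <- c()
    term_R <- term_U <- c()
    for (i in seq_len(k)) {
      rn <- paste0("experiment", i, ":R_c")
      un <- paste0("experiment", i, ":U_c")
      beta <- c(beta, setNames(c(ests[i], 0), c(rn, un)))
      term_R[as.character(i)] <- rn
      term_U[as.character(i)] <- un
    }
    fit_result(beta, diag(se^2, length(beta)),
               term_index = list(R = term_R, U = term_U))
  }
  # identical estimates and errors: one group
  g1 <- pairwise_groupings(mk_fit(rep(1, 5), se = 1))
  expect_true(all(g1$estimates$group == "a"))
  expect_equal(g1$n_comparisons, 10L)
  expect_false(any(g1$pairwise$significant))
  # far-apart estimates with tiny errors: all distinct groups
  g2 <- pairwise_groupings(mk_fit(c(0, 10), se = 0.01))
  expect_setequal(g2$estimates$group, c("a", "b"))
  expect_true(all(g2$pairwise$significant))
  # Bonferroni: adjusted z for 10 comparisons at alpha 0.05
  g3 <- pairwise_groupings(mk_fit(rep(0, 5), se = 1))
  width <- g3$pairwise$ci_hi[1] - g3$pairwise$estimate[1]
  expect_equal(width, qnorm(1 - 0.05 / 20) * g3$pairwise$se[1],
               tolerance = 1e-10)
})

test_that("split-vs-lumped LRT is nested, structurally counted, and
           powered against unequal within-class values", {
  recs <- sim_records(archetype_human_like(), experiments = 2:3, nsub = 6,
                      seed0 = 23)
  tab <- prepare_table(recs)
  lrt <- split_value_lrt(tab)
  expect_gte(lrt$loglik_split, lrt$loglik_lumped)
  expect_gte(lrt$chi2, 0)
  # in this fixture every subject saw the experiments in the same order, so
  # order interactions are aliased in both models; the split model then adds
  # exactly 2 estimable value coefficients per experiment (4 values minus
  # the experiment main effect, minus the 1 lumped binary coefficient)
  expect_equal(lrt$df, 4L)

  # dual route for the structural df on an order-randomized study: the
  # parameter-count difference must equal the column-rank difference of the
  # two model matrices
  st <- run_study(study_config(n_subjects = 8, master_seed = 5))
  tab2 <- prepare_table(st$records)
  lrt2 <- split_value_lrt(tab2)
  tab2$Rv <- factor(tab2$reliable_value)
  rank_of <- function(f) qr(model.matrix(f, tab2))$rank
  r_split <- rank_of(~ 0 + experiment + subject + experiment:U_c +
                       experiment:Rv + experiment:U_c:order_c +
                       experiment:Rv:order_c)
  r_lumped <- rank_of(~ 0 + experiment + subject + experiment:U_c +
                        experiment:R_c + experiment:U_c:order_c +
                        experiment:R_c:order_c)
  expect_equal(lrt2$df, r_split - r_lumped)
  expect_gte(lrt2$loglik_split, lrt2$loglik_lumped)

  # power: attacks generated with unequal rates on the two good values
  d <- design_table(nsub = 8, experiments = 2:3)
  eta <- ifelse(d$reliable_value == "G1", 1.5,
                ifelse(d$reliable_value == "G2", -0.5, -1.5))
  sig <- withr::with_seed(77, {
    vapply(1:50, function(i) {
      d$attacked <- rbinom(nrow(d), 1, plogis(eta))
      split_value_lrt(d)$p < 0.001
    }, TRUE)
  })
  expect_gte(mean(sig), 0.95)
})

test_that("parameter recovery: 95% Wald CIs cover the generating trait
           coefficients between 90% and 98% of the time", {
  d <- design_table(nsub = 8, experiments = 1:5)
  f <- attacked ~ 0 + experiment + subject + experiment:U_c +
    experiment:R_c + experiment:U_c:order_c + experiment:R_c:order_c
  X <- model.matrix(f, d)
  trait_cols <- grep(":(R_c|U_c)$", colnames(X), value = TRUE)
  beta_true <- withr::with_seed(99, {
    b <- setNames(runif(ncol(X), -1, 1), colnames(X))
    b[grep(":R_c$", colnames(X))] <- 1.5
    b[grep(":U_c$", colnames(X))] <- 0.3
    b
  })
  eta <- drop(X %*% beta_true)
  cover <- withr::with_seed(101, {
    replicate(200, {
      d$attacked <- rbinom(nrow(d), 1, plogis(eta))
      fit <- fit_model(d)
      nm <- intersect(trait_cols, names(fit$beta))
      se <- sqrt(diag(fit$cov)[nm])
      mean(abs(fit$beta[nm] - beta_true[nm]) <= qnorm(0.975) * se)
    })
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})
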