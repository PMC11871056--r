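# Shared small dataset with real species structure, reused across blocks to
# avoid refitting simulators.
sim3 <- local({
  p <- list(
    a = tiny_species("Alpha", n_individuals = 4, bill_length = 28,
                     deposition_mean = 5),
    b = tiny_species("Beta", n_individuals = 4, bill_length = 20,
                     deposition_mean = 20),
    c = tiny_species("Gamma", n_individuals = 4, bill_length = 14,
                     deposition_mean = 40)
  )
  d <- simulate_dataset(p, n_trials = 5, seed = 33)
  an <- assemble_analysis(d$trials, d$birds, d$flowers)
  list(data = d, analysis = an)
})

test_that("model specification enforces family/response compatibility", {
  expect_error(model_spec("y", "gamma", zi = "species"), "Tweedie")
  td <- sim3$analysis$trial_data
  gamma_zero <- model_spec("patch_area", "gamma", "species", "bird")
  expect_error(fit_glmm(gamma_zero, td), "strictly positive")
  nb_cont <- model_spec("feeding_efficiency", "nbinom2", "species", "bird")
  expect_error(fit_glmm(nb_cont, td), "integer counts")
})

test_that("intercept-only Gamma/log fit recovers ln of the sample mean", {
  set.seed(41)
  dat <- data.frame(y = rgamma(150, shape = 4, rate = 2))
  f <- fit_glmm(model_spec("y", "gamma", fixed = "1", random = "none"), dat)
  expect_equal(f$coefficients$estimate_link[1], log(mean(dat$y)),
               tolerance = 1e-6)
})

test_that("intercept-only NB2 fit matches a direct likelihood maximization", {
  set.seed(42)
  dat <- data.frame(y = rnbinom(300, mu = 12, size = 1.4))
  f <- fit_glmm(model_spec("y", "nbinom2", fixed = "1", random = "none"), dat)
  # independent route: Nelder-Mead on the NB log-likelihood in (log mu, log theta)
  nll <- function(par) -sum(dnbinom(dat$y, mu = exp(par[1]),
                                    size = exp(par[2]), log = TRUE))
  o <- optim(c(0, 0), nll, control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f$coefficients$estimate_link[1], o$par[1], tolerance = 1e-4)
  expect_equal(log(glmmTMB::sigma(f$fit)), o$par[2], tolerance = 1e-3)
})

test_that("response-scale coefficients are exactly exp of link-scale ones", {
  fits <- fit_standard_models(sim3$analysis,
                              which = c("dep_species", "feedeff_species"))
  for (f in fits)
    expect_equal(f$coefficients$estimate_response,
                 exp(f$coefficients$estimate_link), tolerance = 1e-15)
})

test_that("species contrasts on known log-scale offsets are recovered within 2 SE", {
  # three species with deposition means 5/20/40: log contrasts log(5/20), log(5/40)
  f <- fit_glmm(model_spec("stigma_pollen_count", "nbinom2", "species", "bird"),
                sim3$analysis$trial_data)
  pc <- pairwise_contrasts(f, "species")
  em <- summary(emmeans::contrast(emmeans::emmeans(f$fit, "species"),
                                  method = "pairwise"))
  truth <- c("Alpha - Beta" = log(5 / 20), "Alpha - Gamma" = log(5 / 40),
             "Beta - Gamma" = log(20 / 40))
  for (i in seq_len(nrow(pc))) {
    expect_lt(abs(pc$estimate_link[i] - truth[[pc$pair[i]]]), 2 * em$SE[i])
  }
})

test_that("Cohen's d matches its defining formula and edge cases", {
  set.seed(43)
  x <- rnorm(20, 3, 2); y <- rnorm(25, 1, 1.5)
  sp <- sqrt(((19) * var(x) + (24) * var(y)) / 43)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 1, 2), c(1, 2, 3)), -1) # one pooled SD apart
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "two observations")
})

test_that("Tukey adjustment reduces to no adjustment at k = 2 and never helps a pair", {
  td <- sim3$analysis$trial_data
  two <- td[td$species != "Gamma", ]
  f2 <- fit_glmm(model_spec("stigma_pollen_count", "nbinom2", "species", "bird"),
                 two)
  pc2 <- pairwise_contrasts(f2, "species")
  raw2 <- summary(emmeans::contrast(emmeans::emmeans(f2$fit, "species"),
                                    method = "pairwise", adjust = "none"))
  expect_equal(pc2$p_adjusted, raw2$p.value, tolerance = 1e-10)

  f3 <- fit_glmm(model_spec("stigma_pollen_count", "nbinom2", "species", "bird"),
                 td)
  pc3 <- pairwise_contrasts(f3, "species")
  raw3 <- summary(emmeans::contrast(emmeans::emmeans(f3$fit, "species"),
                                    method = "pairwise", adjust = "none"))
  expect_true(all(pc3$p_adjusted >= raw3$p.value - 1e-12))
})

test_that("a single 1-df type-III test equals the two-sided Wald z test", {
  td <- sim3$analysis$trial_data
  td$abs_PC1 <- td$receiver_abs_PC1
  f <- fit_glmm(model_spec("stigma_pollen_count", "nbinom2", "abs_PC1",
                           random = "none"), td)
  p_anova <- type3_test(f, "abs_PC1")
  i <- match("abs_PC1", f$coefficients$term)
  p_wald <- 2 * pnorm(-abs(f$coefficients$z[i]))
  expect_equal(p_anova, p_wald, tolerance = 1e-10)
  expect_error(type3_test(f, "nope"), "not in the model")
})

test_that("trigamma R2 components behave as the variance decomposition requires", {
  td <- sim3$analysis$trial_data
  # intercept-only: no fixed-effect variance, marginal R2 is exactly 0
  f0 <- fit_glmm(model_spec("stigma_pollen_count", "nbinom2", "1", "bird"), td)
  r0 <- r2_nakagawa(f0)
  expect_equal(r0$marginal, 0, tolerance = 1e-12)
  expect_gte(r0$conditional, r0$marginal)

  # no random effects: marginal equals conditional
  f1 <- fit_glmm(model_spec("stigma_pollen_count", "nbinom2", "species",
                            random = "none"), td)
  r1 <- r2_nakagawa(f1)
  expect_equal(r1$marginal, r1$conditional)
  expect_true(r1$marginal >= 0 && r1$conditional <= 1)

  f2 <- fit_glmm(model_spec("feeding_efficiency", "gamma", "species", "bird"), td)
  r2 <- r2_nakagawa(f2)
  expect_true(r2$marginal >= 0 && r2$marginal <= r2$conditional &&
                r2$conditional <= 1)
})

test_that("the NB trigamma latent variance approaches 1/mu for near-Poisson data", {
  set.seed(44)
  dat <- data.frame(y = rpois(4000, 25))
  f <- fit_glmm(model_spec("y", "nbinom2", "1", "none"), dat)
  mu_hat <- mean(predict(f$fit, type = "response"))
  theta_hat <- glmmTMB::sigma(f$fit)
  vd <- trigamma(1 / (1 / mu_hat + 1 / theta_hat))
  # psi_1(x) ~ 1/x + 1/(2x^2): within 5% of the delta-method 1/mu for mu >= 10
  expect_lt(abs(vd - 1 / mu_hat) / (1 / mu_hat), 0.05)
})

test_that("zero-inflated Tweedie recovers structural-zero rates within 2 SE", {
  set.seed(45)
  n <- 900
  sp <- factor(rep(c("A", "B", "C"), each = n / 3))
  zi_true <- c(A = 0.35, B = 0.15, C = 0.05)
  mu <- exp(c(A = 1.5, B = 2.0, C = 2.2))[sp]
  # compound Poisson-gamma with a high event rate, so the family's own zero
  # mass (exp(-6) < 0.3%) is negligible and the structural split identifiable
  npois <- rpois(n, 6)
  y <- ifelse(npois == 0, 0, rgamma(n, shape = npois * 2, scale = mu / (6 * 2)))
  y[runif(n) < zi_true[sp]] <- 0
  dat <- data.frame(y = y, species = sp)
  f <- fit_glmm(model_spec("y", "tweedie", "species", "none", zi = "species"),
                dat)
  zi <- summary(f$fit)$coefficients$zi
  est <- plogis(zi[, "Estimate"])
  # delta-method SE on the probability scale
  se <- zi[, "Std. Error"] * est * (1 - est)
  for (i in 1:3) {
    expect_lt(abs(est[i] - zi_true[i]), 2 * se[i])
  }
})

test_that("trial-order pre-check flags an injected trend and passes clean data", {
  clean <- trial_effect_check(sim3$data$trials)
  expect_named(clean, c("table", "include_trial"))
  expect_setequal(clean$table$term, c("trial", "species", "trial:species"))
  expect_true(all(clean$table$p >= 0 & clean$table$p <= 1))

  # inject a strong trial trend: +1 log unit per trial
  tr <- sim3$data$trials
  tr$stigma_pollen_count <- as.integer(round(
    tr$stigma_pollen_count * exp(tr$trial_number - 1) / 20
  ) + rpois(nrow(tr), 2 * exp(tr$trial_number - 1)))
  trended <- trial_effect_check(tr)
  expect_lt(trended$table$p[trended$table$term == "trial"], 1e-3)
  expect_true(trended$include_trial)
})

test_that("the standard model battery fits and tabulates cleanly", {
  fits <- suppressWarnings(
    fit_standard_models(sim3$analysis,
                        which = c("dep_species", "dep_matching",
                                  "feedeff_matching"))
  )
  tab <- models_table(fits)
  expect_true(all(c("model", "term", "estimate_link", "p", "pair",
                    "p_pairwise", "cohens_d", "r2_marginal") %in% names(tab)))
  # matching models carry both PC terms; species model carries 3 pairs
  expect_setequal(tab$term[tab$model == "feedeff_matching"],
                  c("abs_PC1", "abs_PC2"))
  expect_equal(sum(tab$model == "dep_species" & !is.na(tab$pair)), 3)
  pr <- tab[tab$model == "dep_species" & !is.na(tab$pair), ]
  expect_equal(pr$estimate_response, exp(pr$estimate_link), tolerance = 1e-12)
})
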