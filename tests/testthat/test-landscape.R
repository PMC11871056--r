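mk_visits <- function(flowers, species = "Sp") {
  data.frame(visit_id = sprintf("v%02d", seq_along(flowers)),
             species = species, site_id = "s1",
             flowers_probed = as.integer(flowers), stringsAsFactors = FALSE)
}

test_that("degenerate pools give exact per-run statistics", {
  v <- mk_visits(rep(2, 4))
  runs <- run_permutations(v, list(Sp = rep(3, 5)), R = 7, seed = 1)
  expect_equal(nrow(runs), 7)
  expect_true(all(runs$mean_per_plant == 6)) # d * f
  expect_true(all(runs$landscape_total == 24)) # d * f * n
  z <- run_permutations(v, list(Sp = c(0, 0, 0)), R = 5, seed = 1)
  expect_true(all(z$mean_per_plant == 0) && all(z$landscape_total == 0))
})

test_that("a species with visits but no pool is reported by name", {
  v <- rbind(mk_visits(1:2, "Have"), mk_visits(1:2, "Lack"))
  expect_error(run_permutations(v, list(Have = c(1, 2)), R = 2, seed = 1),
               "Lack")
  expect_error(closed_form_expectation(v, list(Have = c(1, 2))), "Lack")
})

test_that("closed-form moments match exhaustive enumeration on small instances", {
  # pool {2,4}, visits probing {1,3}: E[mean] = mean(pool) * mean(f) = 3 * 2
  v <- mk_visits(c(1, 3))
  cf <- closed_form_expectation(v, list(Sp = c(2, 4)))
  expect_equal(cf$e_mean_per_plant, 6)
  expect_equal(cf$e_landscape_total, 12)

  # exhaustive enumeration over all pool-to-visit assignments
  enumerate_moments <- function(pool, flowers) {
    n <- length(flowers)
    grid <- expand.grid(rep(list(seq_along(pool)), n))
    totals <- as.matrix(grid)
    vals <- matrix(pool[totals], nrow(grid), n)
    tot <- vals %*% flowers
    mean_pp <- tot / n
    list(e_mean = mean(mean_pp), e_tot = mean(tot),
         v_mean = mean(mean_pp^2) - mean(mean_pp)^2,
         v_tot = mean(tot^2) - mean(tot)^2)
  }
  for (case in list(list(pool = c(0, 2, 5), f = c(1, 2, 4)),
                    list(pool = c(1, 1, 3, 8), f = c(2, 2)),
                    list(pool = 7, f = c(1, 3, 5)))) {
    v <- mk_visits(case$f)
    cf <- closed_form_expectation(v, list(Sp = case$pool))
    en <- enumerate_moments(case$pool, case$f)
    expect_equal(cf$e_mean_per_plant, en$e_mean, tolerance = 1e-12)
    expect_equal(cf$e_landscape_total, en$e_tot, tolerance = 1e-12)
    expect_equal(cf$var_mean_per_plant, en$v_mean, tolerance = 1e-12)
    expect_equal(cf$var_landscape_total, en$v_tot, tolerance = 1e-12)
  }
  # single visit, single-value pool: variance exactly 0
  cf1 <- closed_form_expectation(mk_visits(3), list(Sp = 5))
  expect_equal(cf1$var_landscape_total, 0)
})

test_that("Monte-Carlo means converge to the closed form within 3 MC-SE", {
  set.seed(50)
  v <- mk_visits(sample(1:6, 30, replace = TRUE))
  pool <- rnbinom(12, mu = 20, size = 0.8)
  R <- 1e4
  runs <- run_permutations(v, list(Sp = pool), R = R, seed = 2)
  cf <- closed_form_expectation(v, list(Sp = pool))
  mcse <- sqrt(cf$var_mean_per_plant / R)
  expect_lt(abs(mean(runs$mean_per_plant) - cf$e_mean_per_plant), 3 * mcse)
  mcse_t <- sqrt(cf$var_landscape_total / R)
  expect_lt(abs(mean(runs$landscape_total) - cf$e_landscape_total), 3 * mcse_t)
  # observed run-to-run variance close to the exact variance
  expect_lt(abs(var(runs$mean_per_plant) / cf$var_mean_per_plant - 1), 0.1)
})

test_that("per-flower resampling keeps the expectation but shrinks the variance", {
  set.seed(51)
  v <- mk_visits(sample(2:6, 25, replace = TRUE))
  pool <- rnbinom(10, mu = 15, size = 1)
  R <- 4000
  pv <- run_permutations(v, list(Sp = pool), R = R, seed = 3)
  pf <- run_permutations(v, list(Sp = pool), R = R, seed = 3, per_flower = TRUE)
  cf <- closed_form_expectation(v, list(Sp = pool))
  mcse <- sqrt(cf$var_mean_per_plant / R)
  expect_lt(abs(mean(pf$mean_per_plant) - cf$e_mean_per_plant), 4 * mcse)
  expect_lt(var(pf$mean_per_plant), var(pv$mean_per_plant))
})

test_that("scaling every flowers-probed count scales both expectations exactly", {
  v <- mk_visits(c(2, 3, 5, 1))
  pool <- list(Sp = c(0, 4, 9))
  cf1 <- closed_form_expectation(v, pool)
  v3 <- v; v3$flowers_probed <- v$flowers_probed * 3L
  cf3 <- closed_form_expectation(v3, pool)
  expect_equal(cf3$e_mean_per_plant, 3 * cf1$e_mean_per_plant)
  expect_equal(cf3$e_landscape_total, 3 * cf1$e_landscape_total)
})

test_that("summaries over runs match direct mean/SE computation", {
  runs <- data.frame(run = 1:4, species = "Sp", n_visits = 2,
                     mean_per_plant = c(1, 2, 3, 4),
                     landscape_total = c(2, 4, 6, 8))
  s <- summarize_permutations(runs)
  expect_equal(s$mean_per_plant, 2.5)
  expect_equal(s$se_mean_per_plant, sd(1:4) / 2, tolerance = 1e-12)
  expect_equal(round(s$se_mean_per_plant, 4), 0.6455)
  const <- runs; const$mean_per_plant <- 5; const$landscape_total <- 10
  sc <- summarize_permutations(const)
  expect_equal(sc$se_mean_per_plant, 0)
  expect_error(summarize_permutations(runs[1, ]), "two runs")
})

test_that("species comparisons separate shifted pools and collapse at k = 2", {
  set.seed(52)
  v <- rbind(mk_visits(sample(2:5, 40, TRUE), "Lo"),
             mk_visits(sample(2:5, 40, TRUE), "Hi"))
  pools <- list(Lo = rnbinom(15, mu = 5, size = 1),
                Hi = rnbinom(15, mu = 5, size = 1) + 100)
  runs <- run_permutations(v, pools, R = 100, seed = 4)
  cmp <- compare_species(runs, "mean_per_plant")
  expect_lt(cmp$contrasts$p_adjusted[1], 1e-6)
  expect_gt(abs(cmp$contrasts$cohens_d[1]), 5)
  # k = 2: Tukey-adjusted p equals the unadjusted pairwise p (t test)
  d <- data.frame(y = runs$mean_per_plant, g = runs$species)
  p_t <- t.test(y ~ g, data = d, var.equal = TRUE)$p.value
  expect_equal(cmp$contrasts$p_adjusted[1], p_t, tolerance = 1e-9)

  fp <- compare_species(metric = "flowers_probed", visits = v)
  expect_true(fp$anova$p > 0 && fp$anova$p <= 1)
  expect_error(compare_species(runs[runs$run == 1, ], "mean_per_plant"),
               "two runs")
})

test_that("independent seeds agree within combined Monte-Carlo error", {
  set.seed(53)
  v <- mk_visits(sample(1:8, 50, TRUE))
  pool <- list(Sp = rnbinom(20, mu = 30, size = 0.7))
  R <- 2000
  r1 <- run_permutations(v, pool, R = R, seed = 101)
  r2 <- run_permutations(v, pool, R = R, seed = 202)
  cf <- closed_form_expectation(v, pool)
  combined_se <- sqrt(2 * cf$var_mean_per_plant / R)
  expect_lt(abs(mean(r1$mean_per_plant) - mean(r2$mean_per_plant)),
            4 * combined_se)
})
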