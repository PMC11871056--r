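#' Per-species pools of measured per-flower deposition values
#'
#' @param trials Trials table with `species` and `stigma_pollen_count`.
#' @return Named list of numeric vectors (one pool per species). Zero
#'   counts are retained: they are measured outcomes and dropping them
#'   would bias landscape totals upward.
#' @export
deposition_pools <- function(trials) {
  split(as.numeric(trials$stigma_pollen_count), trials$species)
}

#' Resample experimental deposition onto camera-trap visits
#'
#' The scaling estimator: in each of `R` runs, every camera-trap visit is
#' assigned a per-flower deposition value drawn uniformly with replacement
#' from the experimental pool of the visiting species (pools are never
#' mixed across species). The visit's plant-level deposition is the
#' assigned value times the number of flowers probed; per species and run,
#' the mean over visits gives the mean per-plant deposition and the sum
#' gives the landscape total.
#'
#' @param visits Visit table with `species` and `flowers_probed` (>= 1).
#' @param pools Named list of per-species deposition values (see
#'   [deposition_pools()]); every species present in `visits` needs a
#'   non-empty pool.
#' @param R Number of runs (default 100).
#' @param seed Integer seed; fixed seed reproduces the runs exactly.
#' @param per_flower If `TRUE`, a fresh deposition value is drawn for every
#'   probed flower within a visit instead of one per visit. The expectation
#'   is identical; the run-to-run variance is smaller.
#' @return Data.frame with one row per run x species: `run`, `species`,
#'   `n_visits`, `mean_per_plant`, `landscape_total`.
#' @export
run_permutations <- function(visits, pools, R = 100, seed = 1,
                             per_flower = FALSE) {
  if (R < 1) stop("`R` must be >= 1")
  if (any(visits$flowers_probed < 1))
    stop("every visit probes at least one flower")
  sp <- unique(as.character(visits$species))
  missing_pool <- sp[!vapply(sp, function(s) length(pools[[s]]) > 0, logical(1))]
  if (length(missing_pool))
    stop("species with visits but no deposition pool: ",
         paste(missing_pool, collapse = ", "))
  set.seed(child_seed(seed, .stage_ids[["permutation"]]))
  out <- lapply(sp, function(s) {
    f <- as.numeric(visits$flowers_probed[visits$species == s])
    n <- length(f)
    pool <- as.numeric(pools[[s]])
    if (per_flower) {
      # one draw per probed flower; visit totals are sums within visits
      per_run <- vapply(seq_len(R), function(r) {
        d <- sample(pool, sum(f), replace = TRUE)
        grp <- rep.int(seq_len(n), f)
        tot <- vapply(split(d, grp), sum, numeric(1))
        c(mean(tot), sum(tot))
      }, numeric(2))
    } else {
      draws <- matrix(sample(pool, R * n, replace = TRUE), nrow = R)
      per_visit <- sweep(draws, 2, f, `*`)
      per_run <- rbind(rowMeans(per_visit), rowSums(per_visit))
    }
    data.frame(run = seq_len(R), species = s, n_visits = n,
               mean_per_plant = per_run[1, ],
               landscape_total = per_run[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exact moments of the resampling estimator
#'
#' Analytic expectation and variance of the per-run statistics under
#' uniform-with-replacement sampling from the pools, independent across
#' visits. With `m = mean(pool)`, `v = population variance of the pool`
#' (divisor `length(pool)`), and flowers-probed values `f_i`:
#' `E[mean_per_plant] = m * mean(f)`, `E[landscape_total] = m * sum(f)`,
#' `Var[landscape_total] = v * sum(f_i^2)` and
#' `Var[mean_per_plant] = v * sum(f_i^2) / n^2`.
#'
#' @inheritParams run_permutations
#' @return Data.frame per species: expectations and exact variances of
#'   both statistics.
#' @export
closed_form_expectation <- function(visits, pools) {
  sp <- unique(as.character(visits$species))
  missing_pool <- sp[!vapply(sp, function(s) length(pools[[s]]) > 0, logical(1))]
  if (length(missing_pool))
    stop("species with visits but no deposition pool: ",
         paste(missing_pool, collapse = ", "))
  out <- lapply(sp, function(s) {
    f <- as.numeric(visits$flowers_probed[visits$species == s])
    pool <- as.numeric(pools[[s]])
    m <- mean(pool)
    v <- mean(pool^2) - m^2 # population variance: draws are uniform over the pool
    n <- length(f)
    data.frame(species = s,
               e_mean_per_plant = m * mean(f),
               e_landscape_total = m * sum(f),
               var_mean_per_plant = v * sum(f^2) / n^2,
               var_landscape_total = v * sum(f^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize permutation runs per species
#'
#' @param runs Output of [run_permutations()] with at least two runs.
#' @return Data.frame per species: number of runs `R`, mean and SE (SD over
#'   runs / sqrt(R)) of `mean_per_plant` and `landscape_total`, and
#'   `n_visits`.
#' @export
summarize_permutations <- function(runs) {
  if (length(unique(runs$run)) < 2L)
    stop("at least two runs are needed for an SE over runs")
  out <- lapply(split(runs, runs$species), function(d) {
    R <- nrow(d)
    data.frame(
      species = d$species[1], R = R, n_visits = d$n_visits[1],
      mean_per_plant = mean(d$mean_per_plant),
      se_mean_per_plant = stats::sd(d$mean_per_plant) / sqrt(R),
      landscape_total = mean(d$landscape_total),
      se_landscape_total = stats::sd(d$landscape_total) / sqrt(R),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interspecific comparison of permutation outputs or visit data
#'
#' Type-III ANOVA across species with Tukey-adjusted pairwise contrasts and
#' Cohen's d. For the permutation metrics each run contributes one
#' observation per species (runs treated as i.i.d., which understates the
#' uncertainty from the finite experimental pools); for `flowers_probed`
#' the raw visit records are the observations.
#'
#' @param runs Output of [run_permutations()] (ignored for
#'   `metric = "flowers_probed"`).
#' @param metric `"mean_per_plant"`, `"landscape_total"` or
#'   `"flowers_probed"`.
#' @param visits Visit table, required for `metric = "flowers_probed"`.
#' @return List: `anova` (data.frame with F, df, p), `contrasts`
#'   (data.frame `pair`, `estimate`, `p_adjusted`, `cohens_d`).
#' @export
compare_species <- function(runs = NULL,
                            metric = c("mean_per_plant", "landscape_total",
                                       "flowers_probed"),
                            visits = NULL) {
  metric <- match.arg(metric)
  if (metric == "flowers_probed") {
    if (is.null(visits)) stop("`visits` is required for the flowers_probed metric")
    d <- data.frame(y = as.numeric(visits$flowers_probed),
                    species = factor(visits$species))
  } else {
    if (is.null(runs)) stop("`runs` is required for permutation metrics")
    if (length(unique(runs$run)) < 2L) stop("at least two runs are required")
    d <- data.frame(y = runs[[metric]], species = factor(runs$species))
  }
  if (nlevels(d$species) < 2L) stop("at least two species are required")
  contrasts(d$species) <- stats::contr.sum(nlevels(d$species))
  fit <- stats::lm(y ~ species, data = d)
  a <- car::Anova(fit, type = "III")
  arow <- a["species", ]
  anova_tab <- data.frame(term = "species", F = arow[["F value"]],
                          df = arow[["Df"]], df_resid = a["Residuals", "Df"],
                          p = arow[["Pr(>F)"]], stringsAsFactors = FALSE)
  em <- emmeans::emmeans(fit, specs = "species")
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  dd <- vapply(as.character(pr$contrast), function(ct) {
    lv <- trimws(strsplit(ct, " - ", fixed = TRUE)[[1]])
    lv <- gsub("^\\(|\\)$", "", lv)
    cohens_d(d$y[as.character(d$species) == lv[1]],
             d$y[as.character(d$species) == lv[2]])
  }, numeric(1))
  list(anova = anova_tab,
       contrasts = data.frame(pair = as.character(pr$contrast),
                              estimate = pr$estimate,
                              p_adjusted = pr$p.value,
                              cohens_d = dd,
                              stringsAsFactors = FALSE))
}
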