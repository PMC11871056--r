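#' Specify a pollen-transfer / feeding-efficiency GLMM
#'
#' All models use a log link. Counts (stigma pollen grains) use the
#' negative binomial (NB2: variance `mu + mu^2/theta`); non-negative
#' continuous responses with exact zeros (anther-contact duration, patch
#' area) use the Tweedie compound Poisson-gamma with power in (1, 2),
#' optionally with a per-species zero-inflation component; strictly
#' positive responses (feeding duration, feeding efficiency) use the Gamma.
#'
#' @param response Name of the response column.
#' @param family One of `"nbinom2"`, `"tweedie"`, `"gamma"`.
#' @param fixed Character vector of fixed-effect terms (e.g. `"species"`,
#'   `"abs_PC1"`).
#' @param random Random-intercept structure: `"bird"` for `(1 | bird_id)`,
#'   `"bird_in_species"` for `(1 | species / bird_id)`, or `"none"`.
#' @param zi Zero-inflation: `"none"` or `"species"` (a structural-zero
#'   probability per species; only meaningful with the Tweedie family).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("nbinom2", "tweedie", "gamma"),
                       fixed = "species",
                       random = c("bird", "bird_in_species", "none"),
                       zi = c("none", "species")) {
  family <- match.arg(family)
  random <- match.arg(random)
  zi <- match.arg(zi)
  if (zi == "species" && family != "tweedie")
    stop("per-species zero inflation is only used with the Tweedie family")
  structure(list(response = response, family = family, fixed = fixed,
                 random = random, zi = zi),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(spec$fixed, collapse = " + ")
  re <- switch(spec$random,
               bird = " + (1 | bird_id)",
               bird_in_species = " + (1 | species / bird_id)",
               none = "")
  stats::as.formula(paste(spec$response, "~", rhs, re))
}

#' Fit a specified GLMM
#'
#' Maximum-likelihood fit with the random effects integrated out by the
#' Laplace approximation (via \pkg{glmmTMB}). Response/family compatibility
#' is validated up front; non-convergence is reported through the
#' `convergence` flag and a warning, never silently.
#'
#' @param spec A [model_spec()].
#' @param data Data.frame holding the response, fixed-effect columns and
#'   grouping factors.
#' @return Object of class `pollen_glmm`: list with the underlying fit
#'   (`fit`), the `spec`, a `convergence` flag, and `coefficients` (term,
#'   link-scale estimate, response-scale estimate `exp(beta)`, SE, z, p).
#' @export
fit_glmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  y <- data[[spec$response]]
  if (is.null(y)) stop("response `", spec$response, "` not found in data")
  if (anyNA(y)) stop("response `", spec$response, "` has missing values")
  if (spec$family == "nbinom2" &&
      (any(y < 0) || any(abs(y - round(y)) > 1e-8)))
    stop("negative binomial family needs non-negative integer counts")
  if (spec$family == "tweedie" && any(y < 0))
    stop("Tweedie family needs a non-negative response")
  if (spec$family == "gamma" && any(y <= 0))
    stop("Gamma family needs a strictly positive response; found zeros or negatives")
  fam <- switch(spec$family,
                nbinom2 = glmmTMB::nbinom2(link = "log"),
                tweedie = glmmTMB::tweedie(link = "log"),
                gamma = Gamma(link = "log"))
  zif <- if (spec$zi == "species") ~ 0 + species else ~0
  fit <- glmmTMB::glmmTMB(spec_formula(spec), data = data, family = fam,
                          ziformula = zif)
  conv <- isTRUE(fit$fit$convergence == 0) && !isTRUE(fit$sdr$pdHess == FALSE)
  if (!conv)
    warning("model `", spec$response, "` (", spec$family,
            ") did not converge cleanly; inspect diagnostics")
  cf <- summary(fit)$coefficients$cond
  coefs <- data.frame(
    term = rownames(cf),
    estimate_link = cf[, "Estimate"],
    estimate_response = exp(cf[, "Estimate"]),
    se = cf[, "Std. Error"],
    z = cf[, "z value"],
    p = cf[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  structure(list(fit = fit, spec = spec, convergence = conv,
                 coefficients = coefs, data = data),
            class = "pollen_glmm")
}

#' @export
print.pollen_glmm <- function(x, ...) {
  cat("GLMM:", x$spec$response, "~", paste(x$spec$fixed, collapse = " + "),
      " [", x$spec$family, ", log link",
      if (x$spec$zi != "none") ", ZI by species", "]\n", sep = "")
  cat(if (x$convergence) "converged\n" else "NOT converged\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Type-III Wald chi-square test for a fixed-effect term
#'
#' Each term is tested with all other terms (including any interactions)
#' present, i.e. a Wald chi-square on that term's coefficient block.
#'
#' @param fit A `pollen_glmm` (or bare glmmTMB/lm) fit.
#' @param term Optional term name; if omitted the full ANOVA table is
#'   returned as a data.frame (`term`, `chisq`, `df`, `p`).
#' @return A single p-value when `term` is given, else the table.
#' @export
type3_test <- function(fit, term = NULL) {
  obj <- if (inherits(fit, "pollen_glmm")) fit$fit else fit
  a <- car::Anova(obj, type = "III")
  stat_col <- intersect(c("Chisq", "F value"), colnames(a))[1]
  p_col <- grep("^Pr\\(", colnames(a), value = TRUE)[1]
  tab <- data.frame(term = rownames(a),
                    chisq = a[[stat_col]],
                    df = a$Df,
                    p = a[[p_col]],
                    stringsAsFactors = FALSE)
  tab <- tab[tab$term != "(Intercept)" & tab$term != "Residuals", , drop = FALSE]
  rownames(tab) <- NULL
  if (is.null(term)) return(tab)
  i <- match(term, tab$term)
  if (is.na(i)) stop("term `", term, "` not in the model's fixed effects")
  tab$p[i]
}

#' Cohen's d for two groups
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled SD using (n-1) weights. The sign convention is first group minus
#' second group.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @return Cohen's d (numeric scalar).
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two observations")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero; d is undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Tukey-adjusted pairwise species contrasts with effect sizes
#'
#' Estimated marginal means of the fitted model are contrasted for every
#' pair of factor levels, with p-values adjusted by the studentized-range
#' (Tukey) method. Cohen's d for each pair is computed on the raw response
#' values, not on the link scale.
#'
#' @param fit A `pollen_glmm` fit.
#' @param factor Name of the factor (default `"species"`).
#' @return Data.frame: `pair`, `estimate_link` (difference of link-scale
#'   marginal means), `p_adjusted`, `cohens_d`.
#' @export
pairwise_contrasts <- function(fit, factor = "species") {
  stopifnot(inherits(fit, "pollen_glmm"))
  em <- emmeans::emmeans(fit$fit, specs = factor)
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  resp <- fit$data[[fit$spec$response]]
  grp <- as.character(fit$data[[factor]])
  d <- vapply(as.character(pr$contrast), function(ct) {
    lv <- trimws(strsplit(ct, " - ", fixed = TRUE)[[1]])
    lv <- gsub("^\\(|\\)$", "", lv)
    cohens_d(resp[grp == lv[1]], resp[grp == lv[2]])
  }, numeric(1))
  data.frame(pair = as.character(pr$contrast),
             estimate_link = pr$estimate,
             p_adjusted = pr$p.value,
             cohens_d = d,
             stringsAsFactors = FALSE)
}

#' Marginal and conditional R-squared (trigamma method)
#'
#' Variance-explained measures for log-link GLMMs. With `vf` the variance
#' of the fixed-effect linear predictor, `vr` the summed random-intercept
#' variances and `vd` the observation-level (distribution-specific)
#' variance on the latent log scale:
#' marginal `R2 = vf / (vf + vr + vd)` and conditional
#' `R2 = (vf + vr) / (vf + vr + vd)`.
#'
#' `vd` uses the trigamma method where an analytic form exists: for NB2,
#' `trigamma((1/mu + 1/theta)^-1)`; for Gamma, `trigamma(shape)` with shape
#' `1/sigma^2`. The Tweedie has no trigamma form; the lognormal
#' approximation `log(1 + phi * mu^(p - 2))` is used instead, with `mu` the
#' mean conditional fitted value.
#'
#' @param fit A `pollen_glmm` fit (log link).
#' @return List of class `r2_pair` with `marginal` and `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "pollen_glmm"))
  obj <- fit$fit
  beta <- glmmTMB::fixef(obj)$cond
  X <- stats::model.matrix(obj)
  lp <- drop(X %*% beta)
  vf <- stats::var(lp)
  vc <- glmmTMB::VarCorr(obj)$cond
  vr <- if (length(vc)) sum(vapply(vc, function(m) sum(diag(m)), numeric(1))) else 0
  mu_type <- if (fit$spec$zi != "none") "conditional" else "response"
  mu_bar <- mean(stats::predict(obj, type = mu_type))
  if (!is.finite(mu_bar) || mu_bar <= 0)
    stop("mean fitted value must be positive for the latent-scale variance")
  vd <- switch(fit$spec$family,
    nbinom2 = trigamma(1 / (1 / mu_bar + 1 / glmmTMB::sigma(obj))),
    gamma = trigamma(1 / glmmTMB::sigma(obj)^2),
    tweedie = {
      phi <- glmmTMB::sigma(obj)
      p <- glmmTMB::family_params(obj)[["Tweedie power"]]
      log1p(phi * mu_bar^(p - 2))
    })
  denom <- vf + vr + vd
  structure(list(marginal = vf / denom, conditional = (vf + vr) / denom),
            class = "r2_pair")
}

#' @export
print.r2_pair <- function(x, ...) {
  cat(sprintf("marginal R2 = %.4f, conditional R2 = %.4f\n",
              x$marginal, x$conditional))
  invisible(x)
}

#' Pre-check for a trial-order effect on pollen deposition
#'
#' Birds fed at five flowers in sequence, so pollen could accumulate across
#' trials. Before modelling, the deposition counts are tested for effects
#' of trial number, species and their interaction with a type-III Wald
#' chi-square ANOVA on a negative-binomial GLMM (sum-to-zero contrasts, as
#' type-III tests require in the presence of an interaction). If neither
#' the trial term nor the interaction is significant, trial number is
#' dropped from all downstream models.
#'
#' @param data Data.frame with `stigma_pollen_count`, `trial_number`,
#'   `species` and `bird_id`.
#' @param alpha Significance threshold used for the recommendation
#'   (default 0.05).
#' @return List: `table` (term, chisq, df, p), `include_trial` (logical
#'   recommendation).
#' @export
trial_effect_check <- function(data, alpha = 0.05) {
  need <- c("stigma_pollen_count", "trial_number", "species", "bird_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(
    y = data$stigma_pollen_count,
    trial = factor(data$trial_number),
    species = factor(data$species),
    bird_id = factor(data$bird_id)
  )
  contrasts(d$trial) <- stats::contr.sum(nlevels(d$trial))
  contrasts(d$species) <- stats::contr.sum(nlevels(d$species))
  fit <- glmmTMB::glmmTMB(y ~ trial * species + (1 | bird_id),
                          family = glmmTMB::nbinom2(link = "log"), data = d)
  a <- car::Anova(fit, type = "III")
  tab <- data.frame(term = rownames(a), chisq = a$Chisq, df = a$Df,
                    p = a[["Pr(>Chisq)"]], stringsAsFactors = FALSE)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  rownames(tab) <- NULL
  ptrial <- tab$p[tab$term == "trial"]
  pint <- tab$p[tab$term == "trial:species"]
  list(table = tab, include_trial = (ptrial < alpha) || (pint < alpha))
}

#' The study's eight standard model specifications
#'
#' Five interspecific-difference models (response ~ species, random bird
#' intercept) and three trait-matching models (response ~ absolute PC
#' scores, random bird-within-species intercepts):
#' \describe{
#'   \item{dep_species}{stigma pollen count ~ species; NB2}
#'   \item{contact_species}{anther-contact duration ~ species; ZI Tweedie}
#'   \item{patch_species}{patch area ~ species; ZI Tweedie}
#'   \item{feeddur_species}{feeding duration ~ species; Gamma}
#'   \item{feedeff_species}{feeding efficiency ~ species; Gamma}
#'   \item{patch_matching}{patch area ~ |donor PC1| + |donor PC2|; Tweedie}
#'   \item{dep_matching}{stigma pollen count ~ patch area + |receiver PC1| +
#'     |receiver PC2|; NB2}
#'   \item{feedeff_matching}{feeding efficiency (donor and receiver visits
#'     stacked) ~ |PC1| + |PC2|; Gamma}
#' }
#' @return Named list of [model_spec()] objects.
#' @export
standard_model_specs <- function() {
  list(
    dep_species = model_spec("stigma_pollen_count", "nbinom2", "species", "bird"),
    contact_species = model_spec("anther_contact_s", "tweedie", "species",
                                 "bird", zi = "species"),
    patch_species = model_spec("patch_area", "tweedie", "species", "bird",
                               zi = "species"),
    feeddur_species = model_spec("feeding_duration_s", "gamma", "species", "bird"),
    feedeff_species = model_spec("feeding_efficiency", "gamma", "species", "bird"),
    patch_matching = model_spec("patch_area", "tweedie",
                                c("abs_PC1", "abs_PC2"), "bird_in_species"),
    dep_matching = model_spec("stigma_pollen_count", "nbinom2",
                              c("patch_area", "abs_PC1", "abs_PC2"),
                              "bird_in_species"),
    feedeff_matching = model_spec("feeding_efficiency", "gamma",
                                  c("abs_PC1", "abs_PC2"), "bird_in_species")
  )
}

#' Assemble the per-trial analysis table
#'
#' Merges transfer/feeding metrics with the donor and receiver matching
#' PCAs: each trial row gains `donor_abs_PC1/2` and `receiver_abs_PC1/2`
#' (absolute matching scores for that trial's two flowers). Also builds the
#' stacked feeding table used by the trait-matching feeding-efficiency
#' model, with one row per flower visit (donor and receiver) carrying that
#' visit's own feeding efficiency and matching scores.
#'
#' @param trials,birds,flowers Tables as from [simulate_dataset()].
#' @param feeding_from Passed to [transfer_metrics()].
#' @return List: `trial_data`, `feeding_data`, `donor_pca`, `receiver_pca`,
#'   `donor_matching`, `receiver_matching`, `metrics`.
#' @export
assemble_analysis <- function(trials, birds, flowers,
                              feeding_from = "receiver") {
  met <- transfer_metrics(trials, feeding_from = feeding_from)
  don <- matching_table(trials, birds, flowers, "donor")
  rec <- matching_table(trials, birds, flowers, "receiver")
  don_pca <- run_pca(don[matching_variables("donor")])
  rec_pca <- run_pca(rec[matching_variables("receiver")])
  don_abs <- abs_scores(don_pca, 1:2)
  rec_abs <- abs_scores(rec_pca, 1:2)

  trial_data <- cbind(
    met,
    stigma_pollen_count = trials$stigma_pollen_count,
    donor_abs_PC1 = don_abs[, 1], donor_abs_PC2 = don_abs[, 2],
    receiver_abs_PC1 = rec_abs[, 1], receiver_abs_PC2 = rec_abs[, 2]
  )

  feeding_data <- rbind(
    data.frame(bird_id = met$bird_id, species = met$species,
               trial_number = met$trial_number, visit_role = "donor",
               feeding_efficiency = met$feeding_efficiency_donor,
               abs_PC1 = don_abs[, 1], abs_PC2 = don_abs[, 2],
               stringsAsFactors = FALSE),
    data.frame(bird_id = met$bird_id, species = met$species,
               trial_number = met$trial_number, visit_role = "receiver",
               feeding_efficiency = met$feeding_efficiency_receiver,
               abs_PC1 = rec_abs[, 1], abs_PC2 = rec_abs[, 2],
               stringsAsFactors = FALSE)
  )

  list(trial_data = trial_data, feeding_data = feeding_data,
       donor_pca = don_pca, receiver_pca = rec_pca,
       donor_matching = don, receiver_matching = rec, metrics = met)
}

#' Fit the eight standard models
#'
#' @param analysis Output of [assemble_analysis()].
#' @param which Subset of model names from [standard_model_specs()].
#' @return Named list of `pollen_glmm` fits.
#' @export
fit_standard_models <- function(analysis, which = NULL) {
  specs <- standard_model_specs()
  if (!is.null(which)) specs <- specs[which]
  lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    spec <- specs[[nm]]
    dat <- if (nm == "feedeff_matching") {
      analysis$feeding_data
    } else if (nm %in% c("patch_matching", "dep_matching")) {
      d <- analysis$trial_data
      pref <- if (nm == "patch_matching") "donor_" else "receiver_"
      d$abs_PC1 <- d[[paste0(pref, "abs_PC1")]]
      d$abs_PC2 <- d[[paste0(pref, "abs_PC2")]]
      d
    } else {
      analysis$trial_data
    }
    fit_glmm(spec, dat)
  })
}

#' Tabulate fitted models in the results-table layout
#'
#' One row per model term (and per pairwise species contrast for the
#' species models): link-scale coefficient, response-scale (exponentiated)
#' coefficient, type-III p-value, Tukey-adjusted pairwise p and Cohen's d
#' where applicable, and trigamma marginal/conditional R-squared.
#'
#' @param fits Named list of `pollen_glmm` fits from [fit_standard_models()].
#' @return Data.frame.
#' @export
models_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    r2 <- tryCatch(r2_nakagawa(f), error = function(e) list(marginal = NA, conditional = NA))
    t3 <- type3_test(f)
    term_rows <- data.frame(
      model = nm, response = f$spec$response, family = f$spec$family,
      term = t3$term,
      estimate_link = NA_real_, estimate_response = NA_real_,
      p = t3$p, pair = NA_character_, p_pairwise = NA_real_,
      cohens_d = NA_real_,
      r2_marginal = r2$marginal, r2_conditional = r2$conditional,
      converged = f$convergence,
      stringsAsFactors = FALSE
    )
    # per-term slope estimates for continuous terms
    for (i in seq_len(nrow(term_rows))) {
      j <- match(term_rows$term[i], f$coefficients$term)
      if (!is.na(j)) {
        term_rows$estimate_link[i] <- f$coefficients$estimate_link[j]
        term_rows$estimate_response[i] <- f$coefficients$estimate_response[j]
      }
    }
    if ("species" %in% f$spec$fixed) {
      pc <- pairwise_contrasts(f, "species")
      pair_rows <- data.frame(
        model = nm, response = f$spec$response, family = f$spec$family,
        term = "species", estimate_link = pc$estimate_link,
        estimate_response = exp(pc$estimate_link),
        p = NA_real_, pair = pc$pair, p_pairwise = pc$p_adjusted,
        cohens_d = pc$cohens_d,
        r2_marginal = r2$marginal, r2_conditional = r2$conditional,
        converged = f$convergence,
        stringsAsFactors = FALSE
      )
      term_rows <- rbind(term_rows, pair_rows)
    }
    term_rows
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
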