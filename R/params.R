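#' Species-level simulation parameters
#'
#' Bundles everything the synthetic-data generator needs to emulate one
#' honeyeater species: morphometric distribution, per-flower pollen
#' deposition, pollen-patch and anther-contact behaviour, feeding-bout
#' kinematics, and camera-trap visitation.
#'
#' @param species_label Species name (character scalar).
#' @param n_individuals Number of birds to simulate (>= 1).
#' @param morphometric_means Named numeric vector with elements `mass` (g),
#'   `wing_chord` (mm), `tarsus` (mm), `bill_length` (mm), `bill_width` (mm),
#'   `bill_depth` (mm).
#' @param morphometric_cov Symmetric positive-semidefinite 6x6 covariance
#'   matrix for the morphometrics, in the same order as
#'   `morphometric_means`.
#' @param deposition_mean Mean per-flower stigma pollen deposition (grains).
#' @param deposition_dispersion Negative-binomial size parameter theta (> 0);
#'   counts have variance `mu + mu^2 / theta`.
#' @param patch_zero_prob Probability of a structural zero for the
#'   anther-contact outcome (no contact: zero patch area and zero contact
#'   duration), in `[0, 1]`.
#' @param patch_mean_mm2 Mean pollen-patch area (mm^2) given contact.
#' @param contact_mean_s Mean anther-contact duration (s) given contact.
#' @param feeding_duration_shape,feeding_duration_rate Gamma shape and rate
#'   for feeding-bout duration (s); mean is `shape / rate`.
#' @param lick_rate Mean tongue-licking rate (licks/s) used to generate lick
#'   counts from feeding durations.
#' @param visit_count Number of camera-trap visits recorded for the species
#'   (>= 0).
#' @param flowers_probed_mean Mean number of flowers probed per visit
#'   (>= 1); flowers probed are generated as `1 + Poisson(mean - 1)`.
#' @param indiv_sd_log Standard deviation of the per-individual random
#'   intercept, on the log scale, applied to deposition, patch area and
#'   feeding duration. Set to 0 for no individual heterogeneity.
#'
#' @return An object of class `species_params`.
#' @seealso [default_species_params()], [simulate_birds()],
#'   [simulate_trials()], [simulate_visits()]
#' @export
species_params <- function(species_label,
                           n_individuals,
                           morphometric_means,
                           morphometric_cov,
                           deposition_mean,
                           deposition_dispersion,
                           patch_zero_prob,
                           patch_mean_mm2,
                           contact_mean_s,
                           feeding_duration_shape,
                           feeding_duration_rate,
                           lick_rate,
                           visit_count,
                           flowers_probed_mean,
                           indiv_sd_log = 0.5) {
  morpho_fields <- c("mass", "wing_chord", "tarsus", "bill_length",
                     "bill_width", "bill_depth")
  stopifnot(is.character(species_label), length(species_label) == 1L)
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop("`n_individuals` must be a positive integer")
  m <- morphometric_means[morpho_fields]
  if (anyNA(m))
    stop("`morphometric_means` must be named and contain: ",
         paste(morpho_fields, collapse = ", "))
  cv <- as.matrix(morphometric_cov)
  if (!isTRUE(all.equal(cv, t(cv), tolerance = 1e-8)))
    stop("`morphometric_cov` must be symmetric")
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`morphometric_cov` must be positive semidefinite")
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("`", nm, "` must be a positive number")
  }
  check_pos(deposition_mean + 1e-300, "deposition_mean") # >= 0 allowed
  if (deposition_mean < 0) stop("`deposition_mean` must be >= 0")
  check_pos(deposition_dispersion, "deposition_dispersion")
  if (patch_zero_prob < 0 || patch_zero_prob > 1)
    stop("`patch_zero_prob` must be in [0, 1]")
  check_pos(patch_mean_mm2, "patch_mean_mm2")
  check_pos(contact_mean_s, "contact_mean_s")
  check_pos(feeding_duration_shape, "feeding_duration_shape")
  check_pos(feeding_duration_rate, "feeding_duration_rate")
  check_pos(lick_rate, "lick_rate")
  if (visit_count < 0) stop("`visit_count` must be >= 0")
  if (flowers_probed_mean < 1)
    stop("`flowers_probed_mean` must be >= 1 (a visit probes at least one flower)")
  if (indiv_sd_log < 0) stop("`indiv_sd_log` must be >= 0")

  structure(list(
    species_label = species_label,
    n_individuals = as.integer(n_individuals),
    morphometric_means = m,
    morphometric_cov = cv,
    deposition_mean = deposition_mean,
    deposition_dispersion = deposition_dispersion,
    patch_zero_prob = patch_zero_prob,
    patch_mean_mm2 = patch_mean_mm2,
    contact_mean_s = contact_mean_s,
    feeding_duration_shape = feeding_duration_shape,
    feeding_duration_rate = feeding_duration_rate,
    lick_rate = lick_rate,
    visit_count = as.integer(visit_count),
    flowers_probed_mean = flowers_probed_mean,
    indiv_sd_log = indiv_sd_log
  ), class = "species_params")
}

#' Floral morphometric distribution parameters
#'
#' Means and coefficients of variation for the seven floral linear
#' morphometrics used in bill-corolla matching: total corolla length (TCL),
#' effective corolla length (ECL), corolla width (CW), anther-to-corolla
#' -opening distance (ACO), anther-to-nectary distance (AN),
#' stigma-to-corolla-opening distance (SCO) and stigma-to-nectary distance
#' (SN). All in mm. Anther distances exist only on pollen-donor flowers
#' (anthers intact), stigma distances only on pollen-receiver flowers
#' (emasculated, stigma only).
#'
#' @param means Named numeric vector with elements TCL, ECL, CW, ACO, AN,
#'   SCO, SN (all positive, mm); ECL mean must not exceed TCL mean.
#' @param cv Named numeric vector of coefficients of variation for the same
#'   elements (non-negative).
#' @return An object of class `floral_params`.
#' @export
floral_params <- function(means, cv) {
  fields <- c("TCL", "ECL", "CW", "ACO", "AN", "SCO", "SN")
  m <- means[fields]; v <- cv[fields]
  if (anyNA(m) || anyNA(v))
    stop("`means` and `cv` must be named and contain: ",
         paste(fields, collapse = ", "))
  if (any(m <= 0)) stop("all floral means must be positive")
  if (any(v < 0)) stop("coefficients of variation must be non-negative")
  if (m[["ECL"]] > m[["TCL"]])
    stop("mean ECL cannot exceed mean TCL (the effective corolla is part of the tube)")
  structure(list(means = m, cv = v), class = "floral_params")
}

#' Default species parameters for the three-honeyeater study design
#'
#' Returns the generator's default study conditions: three honeyeater
#' species (spiny-cheeked *Acanthagenys rufogularis*, white-fronted
#' *Purnella albifrons*, yellow-plumed *Ptilotula ornata*) with 3, 8 and 9
#' captive individuals, five two-part trials per bird, camera-trap visit
#' totals of 1258, 146 and 1495, and species mean flowers probed per visit
#' of 5.6, 5.2 and 5.4. Per-flower deposition means are anchored so that
#' mean deposition times mean flowers probed reproduces the study-scale
#' per-plant deposition ordering (A. rufogularis lowest, Pu. albifrons
#' highest per flower, Pi. ornata most visits).
#'
#' @return Named list of three [species_params()] objects.
#' @export
default_species_params <- function() {
  morpho <- function(mass, wing, tarsus, bl, bw, bd) {
    c(mass = mass, wing_chord = wing, tarsus = tarsus,
      bill_length = bl, bill_width = bw, bill_depth = bd)
  }
  # equicorrelated (r = 0.3) covariance from per-trait SDs: PSD by construction
  cov_from_sd <- function(sd) {
    r <- matrix(0.3, 6, 6); diag(r) <- 1
    diag(sd) %*% r %*% diag(sd)
  }
  list(
    "Acanthagenys rufogularis" = species_params(
      species_label = "Acanthagenys rufogularis",
      n_individuals = 3,
      morphometric_means = morpho(43, 118, 27, 28.5, 6.5, 6.0),
      morphometric_cov = cov_from_sd(c(3, 3.5, 1.0, 1.0, 0.30, 0.30)),
      deposition_mean = 4.6, deposition_dispersion = 0.6,
      patch_zero_prob = 0.25, patch_mean_mm2 = 8, contact_mean_s = 0.35,
      feeding_duration_shape = 9, feeding_duration_rate = 6, lick_rate = 6.5,
      visit_count = 1258, flowers_probed_mean = 5.6
    ),
    "Purnella albifrons" = species_params(
      species_label = "Purnella albifrons",
      n_individuals = 8,
      morphometric_means = morpho(17, 72, 20, 20.0, 4.4, 4.2),
      morphometric_cov = cov_from_sd(c(1.5, 2.5, 0.8, 0.8, 0.25, 0.25)),
      deposition_mean = 47, deposition_dispersion = 0.9,
      patch_zero_prob = 0.10, patch_mean_mm2 = 20, contact_mean_s = 0.25,
      feeding_duration_shape = 9, feeding_duration_rate = 3, lick_rate = 10,
      visit_count = 146, flowers_probed_mean = 5.2
    ),
    "Ptilotula ornata" = species_params(
      species_label = "Ptilotula ornata",
      n_individuals = 9,
      morphometric_means = morpho(17, 75, 21, 16.5, 4.2, 4.0),
      morphometric_cov = cov_from_sd(c(1.5, 2.5, 0.8, 0.7, 0.25, 0.25)),
      deposition_mean = 22.6, deposition_dispersion = 0.8,
      patch_zero_prob = 0.10, patch_mean_mm2 = 25, contact_mean_s = 0.55,
      feeding_duration_shape = 9, feeding_duration_rate = 2.9, lick_rate = 10,
      visit_count = 1495, flowers_probed_mean = 5.4
    )
  )
}

#' Default floral parameters for an emu-bush-like flower
#'
#' @return A [floral_params()] object with corolla dimensions typical of
#'   *Eremophila maculata* (total corolla ~24 mm, nectar-accessible portion
#'   ~18 mm, tube width ~5.5 mm, exserted anthers and stigma).
#' @export
default_floral_params <- function() {
  floral_params(
    means = c(TCL = 24, ECL = 18, CW = 4.5, ACO = 6, AN = 21,
              SCO = 6, SN = 21),
    cv = c(TCL = 0.08, ECL = 0.08, CW = 0.12, ACO = 0.15, AN = 0.08,
           SCO = 0.15, SN = 0.08)
  )
}

# Deterministic per-stage child seeds: a single root seed fans out through a
# fixed-multiplier hash so adding a stage never perturbs earlier stages.
# Stage ids are registered here; keep below 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- (abs(as.numeric(seed)) %% 2147483647) * 48271 +
    as.numeric(stage) * 1000003
  as.integer(h %% 2147483647)
}

.stage_ids <- c(birds = 1L, flowers = 2L, trials = 3L, visits = 4L,
                permutation = 5L, models = 6L)
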