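#' Simulate bird morphometrics for one species
#'
#' Draws individuals from a multivariate normal with the species'
#' morphometric mean vector and covariance, truncating every linear
#' measurement at a 0.1 mm (or 0.1 g) floor so all measurements stay
#' positive.
#'
#' @param params A [species_params()] object.
#' @param seed Integer seed; a fixed seed reproduces the table exactly.
#' @param id_prefix Prefix for bird ids (defaults to the first letters of
#'   the species label).
#' @return A data.frame with columns `bird_id`, `species`, `mass`,
#'   `wing_chord`, `tarsus`, `bill_length`, `bill_width`, `bill_depth`.
#' @export
simulate_birds <- function(params, seed, id_prefix = NULL) {
  stopifnot(inherits(params, "species_params"))
  if (is.null(id_prefix)) {
    id_prefix <- toupper(paste(substr(strsplit(params$species_label,
                                               "\\s+")[[1]], 1, 1),
                               collapse = ""))
  }
  n <- params$n_individuals
  set.seed(child_seed(seed, .stage_ids[["birds"]]))
  x <- MASS::mvrnorm(n, mu = params$morphometric_means,
                     Sigma = params$morphometric_cov)
  x <- matrix(x, nrow = n)
  colnames(x) <- names(params$morphometric_means)
  x <- pmax(x, 0.1)
  out <- data.frame(
    bird_id = paste0(id_prefix, seq_len(n)),
    species = params$species_label,
    x,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Draw n flowers of a given role. Each flower gets its own linear
# morphometrics; ECL is clamped at TCL so the nectar-accessible portion
# never exceeds the tube. Role-inappropriate fields are NA (donors carry
# anther distances, receivers stigma distances).
simulate_flowers <- function(floral, role, n, seed, id_start = 1L) {
  stopifnot(inherits(floral, "floral_params"), role %in% c("donor", "receiver"))
  set.seed(seed)
  m <- floral$means; cv <- floral$cv
  draw <- function(f) pmax(stats::rnorm(n, m[[f]], m[[f]] * cv[[f]]), 0.1)
  tcl <- draw("TCL")
  ecl <- pmin(draw("ECL"), tcl)
  out <- data.frame(
    flower_id = sprintf("%s_%04d", substr(role, 1, 1), id_start + seq_len(n) - 1L),
    plant_id = sprintf("plant_%02d", sample.int(12, n, replace = TRUE)),
    role = role,
    TCL = tcl, ECL = ecl, CW = draw("CW"),
    ACO = if (role == "donor") draw("ACO") else NA_real_,
    AN = if (role == "donor") draw("AN") else NA_real_,
    SCO = if (role == "receiver") draw("SCO") else NA_real_,
    SN = if (role == "receiver") draw("SN") else NA_real_,
    stringsAsFactors = FALSE
  )
  out
}

# A jittered-regular polygon (in px) whose shoelace area equals `area_mm2`
# at the given px/mm scale. Vertex count 6..12, random rotation and offset.
make_patch_polygon <- function(area_mm2, scale_px_mm) {
  k <- sample(6:12, 1)
  r_mm <- sqrt(2 * area_mm2 / (k * sin(2 * pi / k)))
  th <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(k) - 1) / k
  cx <- stats::runif(1, 200, 600); cy <- stats::runif(1, 200, 600)
  x <- cx + r_mm * scale_px_mm * cos(th)
  y <- cy + r_mm * scale_px_mm * sin(th)
  paste(sprintf("%.4f %.4f", x, y), collapse = ";")
}

#' Simulate two-part feeding/pollen-transfer trials
#'
#' For each bird and trial, generates a pollen-donor and a pollen-receiver
#' flower visit with the statistical structure the downstream models assume:
#' stigma pollen counts are negative binomial (NB2) around the species mean
#' with a per-bird log-normal random intercept; anther-contact duration and
#' pollen-patch area share a structural-zero event (no anther contact) and
#' are otherwise Gamma; feeding-bout durations are Gamma; anther-contact and
#' feeding frame counts are the durations at 800 frames/s, rounded; lick
#' counts are Poisson at the species licking rate times the feeding
#' duration.
#'
#' @param birds Data.frame from [simulate_birds()] (one species).
#' @param floral A [floral_params()] object.
#' @param params The matching [species_params()] object.
#' @param n_trials Trials per bird (default 5).
#' @param seed Integer seed.
#' @param fps Filming frame rate (frames per second), default 800.
#' @param nectar_volume Standardized nectar volume per flower (microlitre),
#'   default 30.
#' @return A list with `trials` (one row per bird x trial) and `flowers`
#'   (one row per flower, donors and receivers).
#' @export
simulate_trials <- function(birds, floral, params, n_trials = 5, seed,
                            fps = 800, nectar_volume = 30) {
  stopifnot(inherits(params, "species_params"), n_trials >= 1)
  n_birds <- nrow(birds)
  n <- n_birds * n_trials

  donors <- simulate_flowers(floral, "donor", n,
                             child_seed(seed, .stage_ids[["flowers"]]))
  receivers <- simulate_flowers(floral, "receiver", n,
                                child_seed(seed, .stage_ids[["flowers"]]) + 1L)

  set.seed(child_seed(seed, .stage_ids[["trials"]]))
  # per-bird random intercepts (log scale), shared structure across responses
  b_dep <- stats::rnorm(n_birds, 0, params$indiv_sd_log)
  b_patch <- stats::rnorm(n_birds, 0, params$indiv_sd_log)
  b_contact <- stats::rnorm(n_birds, 0, params$indiv_sd_log / 2)
  b_feed <- stats::rnorm(n_birds, 0, params$indiv_sd_log / 2)
  bird_ix <- rep(seq_len(n_birds), each = n_trials)

  mu_dep <- params$deposition_mean * exp(b_dep[bird_ix] -
                                           params$indiv_sd_log^2 / 2)
  dep <- stats::rnbinom(n, mu = mu_dep, size = params$deposition_dispersion)

  contact <- stats::runif(n) >= params$patch_zero_prob
  patch <- ifelse(contact,
                  stats::rgamma(n, shape = 2,
                                rate = 2 / (params$patch_mean_mm2 *
                                              exp(b_patch[bird_ix] -
                                                    params$indiv_sd_log^2 / 2))),
                  0)
  contact_scale <- exp(b_contact[bird_ix] - (params$indiv_sd_log / 2)^2 / 2)
  contact_s <- ifelse(contact,
                      stats::rgamma(n, shape = 2,
                                    rate = 2 / params$contact_mean_s) *
                        contact_scale,
                      0)

  feed_scale <- exp(b_feed[bird_ix] - (params$indiv_sd_log / 2)^2 / 2)
  dur_donor <- stats::rgamma(n, shape = params$feeding_duration_shape,
                             rate = params$feeding_duration_rate) * feed_scale
  dur_recv <- stats::rgamma(n, shape = params$feeding_duration_shape,
                            rate = params$feeding_duration_rate) * feed_scale
  licks <- stats::rpois(n, params$lick_rate * dur_recv)

  image_scale <- stats::runif(n, 35, 45) # px per mm, set from known morphometrics
  poly <- character(n)
  for (i in seq_len(n)) {
    poly[i] <- if (patch[i] > 0) make_patch_polygon(patch[i], image_scale[i]) else ""
  }

  trials <- data.frame(
    bird_id = birds$bird_id[bird_ix],
    species = params$species_label,
    trial_number = rep(seq_len(n_trials), times = n_birds),
    donor_flower_id = donors$flower_id,
    receiver_flower_id = receivers$flower_id,
    anther_contact_frames = as.integer(round(contact_s * fps)),
    feeding_frames_donor = as.integer(pmax(round(dur_donor * fps), 1)),
    feeding_frames_receiver = as.integer(pmax(round(dur_recv * fps), 1)),
    lick_count = as.integer(licks),
    patch_polygon = poly,
    image_scale = image_scale,
    stigma_pollen_count = as.integer(dep),
    nectar_volume = nectar_volume,
    stringsAsFactors = FALSE
  )
  list(trials = trials, flowers = rbind(donors, receivers))
}

#' Simulate camera-trap visit records
#'
#' Each species contributes its configured number of visits; the number of
#' flowers probed per visit is `1 + Poisson(mean - 1)` so every visit probes
#' at least one flower.
#'
#' @param params_list A named list of [species_params()] objects.
#' @param seed Integer seed.
#' @param n_sites Number of camera-trap sites visits are spread over.
#' @return Data.frame with `visit_id`, `species`, `site_id`,
#'   `flowers_probed`. Species with `visit_count = 0` are absent.
#' @export
simulate_visits <- function(params_list, seed, n_sites = 4) {
  if (inherits(params_list, "species_params")) params_list <- list(params_list)
  set.seed(child_seed(seed, .stage_ids[["visits"]]))
  out <- lapply(params_list, function(p) {
    n <- p$visit_count
    if (n == 0L) return(NULL)
    data.frame(
      species = p$species_label,
      site_id = sprintf("site_%d", sample.int(n_sites, n, replace = TRUE)),
      flowers_probed = 1L + stats::rpois(n, p$flowers_probed_mean - 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(visit_id = character(), species = character(),
                      site_id = character(), flowers_probed = integer(),
                      stringsAsFactors = FALSE))
  out$visit_id <- sprintf("v_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("visit_id", "species", "site_id", "flowers_probed")]
}

#' Simulate a complete study dataset
#'
#' Runs the full generator (birds, flowers, trials, camera-trap visits) for
#' a set of species under a single root seed. Per-stage child seeds are
#' derived from the root seed so the tables are individually reproducible.
#'
#' @param params_list Named list of [species_params()]; defaults to the
#'   three-species study design of [default_species_params()].
#' @param floral A [floral_params()] object.
#' @param n_trials Two-part trials per bird (default 5).
#' @param seed Root integer seed.
#' @return List with data.frames `birds`, `flowers`, `trials`, `visits`.
#' @export
simulate_dataset <- function(params_list = default_species_params(),
                             floral = default_floral_params(),
                             n_trials = 5, seed = 1) {
  if (inherits(params_list, "species_params")) {
    params_list <- stats::setNames(list(params_list),
                                   params_list$species_label)
  }
  if (length(params_list) == 0L) stop("`params_list` must contain at least one species")
  birds_l <- list(); trials_l <- list(); flowers_l <- list()
  for (i in seq_along(params_list)) {
    p <- params_list[[i]]
    sp_seed <- child_seed(seed, 100L + i)
    b <- simulate_birds(p, sp_seed)
    tr <- simulate_trials(b, floral, p, n_trials = n_trials, seed = sp_seed)
    # species-unique flower ids
    tag <- sprintf("s%d", i)
    tr$flowers$flower_id <- paste0(tag, "_", tr$flowers$flower_id)
    tr$trials$donor_flower_id <- paste0(tag, "_", tr$trials$donor_flower_id)
    tr$trials$receiver_flower_id <- paste0(tag, "_", tr$trials$receiver_flower_id)
    birds_l[[i]] <- b; trials_l[[i]] <- tr$trials; flowers_l[[i]] <- tr$flowers
  }
  list(
    birds = do.call(rbind, birds_l),
    flowers = do.call(rbind, flowers_l),
    trials = do.call(rbind, trials_l),
    visits = simulate_visits(params_list, seed)
  )
}
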