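# Small parameter sets used across tests: fast to simulate, valid by
# construction.

tiny_species <- function(label = "Testus birdus",
                         n_individuals = 2,
                         bill_length = 20,
                         deposition_mean = 10,
                         deposition_dispersion = 1,
                         patch_zero_prob = 0.2,
                         visit_count = 20,
                         flowers_probed_mean = 3,
                         indiv_sd_log = 0.3,
                         ...) {
  species_params(
    species_label = label,
    n_individuals = n_individuals,
    morphometric_means = c(mass = 20, wing_chord = 80, tarsus = 22,
                           bill_length = bill_length, bill_width = 4.5,
                           bill_depth = 4),
    morphometric_cov = diag(c(2, 3, 0.8, 0.8, 0.2, 0.2))^2,
    deposition_mean = deposition_mean,
    deposition_dispersion = deposition_dispersion,
    patch_zero_prob = patch_zero_prob,
    patch_mean_mm2 = 12, contact_mean_s = 0.4,
    feeding_duration_shape = 9, feeding_duration_rate = 4,
    lick_rate = 9,
    visit_count = visit_count,
    flowers_probed_mean = flowers_probed_mean,
    indiv_sd_log = indiv_sd_log,
    ...
  )
}

small_config <- function(seed = 1, out_dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pipeline_config(
    species_params = list(
      A = tiny_species("Species alpha", n_individuals = 3, bill_length = 30,
                       deposition_mean = 5, visit_count = 25),
      B = tiny_species("Species beta", n_individuals = 3, bill_length = 14,
                       deposition_mean = 25, visit_count = 15)
    ),
    n_trials = 3, permutation_runs = 10, seed = seed,
    models = c("dep_species", "feedeff_species"),
    out_dir = out_dir
  )
}

# Study-shaped three-species design at reduced visitation, for property
# tests that need the qualitative structure but not the full scale.
study_like_params <- function(visit_scale = 1) {
  p <- default_species_params()
  for (nm in names(p)) {
    p[[nm]]$visit_count <- as.integer(round(p[[nm]]$visit_count * visit_scale))
  }
  p
}
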