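# Column schemas for every CSV the pipeline reads or writes. Units:
# masses g, linear measurements mm, durations s, areas mm^2, volumes
# microlitre, deposition counts pollen grains.
pipeline_schemas <- function() {
  list(
    birds = c(bird_id = "character", species = "character", mass = "numeric",
              wing_chord = "numeric", tarsus = "numeric",
              bill_length = "numeric", bill_width = "numeric",
              bill_depth = "numeric"),
    flowers = c(flower_id = "character", plant_id = "character",
                role = "character", TCL = "numeric", ECL = "numeric",
                CW = "numeric", ACO = "numeric", AN = "numeric",
                SCO = "numeric", SN = "numeric"),
    trials = c(bird_id = "character", species = "character",
               trial_number = "integer", donor_flower_id = "character",
               receiver_flower_id = "character",
               anther_contact_frames = "integer",
               feeding_frames_donor = "integer",
               feeding_frames_receiver = "integer",
               lick_count = "integer", patch_polygon = "character",
               image_scale = "numeric", stigma_pollen_count = "integer",
               nectar_volume = "numeric"),
    visits = c(visit_id = "character", species = "character",
               site_id = "character", flowers_probed = "integer")
  )
}

#' Read a validated pipeline table
#'
#' Plain CSV (UTF-8, "." decimal); lines starting with `#` are provenance
#' comments and are skipped. The header must contain every schema column;
#' extra or missing columns are an error naming the offenders, and values
#' that cannot be coerced to the column's type raise an error naming the
#' row and column. An empty-but-headered file yields an empty table.
#'
#' @param path File path.
#' @param schema One of `"birds"`, `"flowers"`, `"trials"`, `"visits"`, or
#'   a named character vector of column types.
#' @return Typed data.frame.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- pipeline_schemas()[[schema]]
  if (is.null(schema)) stop("unknown schema")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  extra <- setdiff(names(df), names(schema))
  if (length(missing) || length(extra))
    stop("schema mismatch in ", basename(path),
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  df <- df[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    raw <- df[[col]]
    blank <- is.na(raw) | !nzchar(trimws(raw)) | trimws(raw) == "NA"
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad))
      stop("non-numeric value in column `", col, "`, row ", bad[1],
           " of ", basename(path), ": '", raw[bad[1]], "'")
    if (type == "integer") {
      off <- which(!blank & abs(val - round(val)) > 1e-8)
      if (length(off))
        stop("non-integer value in column `", col, "`, row ", off[1],
             " of ", basename(path))
      val <- as.integer(round(val))
    }
    val[blank] <- NA
    df[[col]] <- val
  }
  df
}

#' Write a pipeline table with a provenance header
#'
#' @param df Data.frame.
#' @param path Output path.
#' @param seed Root seed recorded in the provenance comment (optional).
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("pollenscape"))
  cat(sprintf("# pollenscape %s%s\n", ver,
              if (!is.null(seed)) paste0(" seed=", seed) else ""),
      file = con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param species_params Named list of [species_params()] objects.
#' @param floral_params A [floral_params()] object.
#' @param n_trials Two-part trials per bird.
#' @param permutation_runs Number of resampling runs for the landscape
#'   stage.
#' @param seed Root seed for every stochastic stage.
#' @param models Names of standard models to fit (see
#'   [standard_model_specs()]).
#' @param feeding_from Feeding-bout source, see [transfer_metrics()].
#' @param out_dir Output directory for CSVs and the run manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(species_params = default_species_params(),
                            floral_params = default_floral_params(),
                            n_trials = 5,
                            permutation_runs = 100,
                            seed = 1,
                            models = names(standard_model_specs()),
                            feeding_from = "receiver",
                            out_dir = tempfile("pollenscape_run_")) {
  if (length(species_params) == 0L)
    stop("configuration error: empty species list")
  structure(list(species_params = species_params,
                 floral_params = floral_params,
                 n_trials = n_trials, permutation_runs = permutation_runs,
                 seed = seed, models = models, feeding_from = feeding_from,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read simulation settings from a YAML configuration file
#'
#' Recognized top-level keys: `seed`, `n_trials`, `permutation_runs`,
#' `feeding_from`, `out_dir`, `models`, and a `species` section mapping
#' species names to overrides of the default [species_params()] fields
#' (e.g. `visit_count`, `deposition_mean`, `n_individuals`).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- default_species_params()
  if (!is.null(y$species)) {
    for (nm in names(y$species)) {
      if (!nm %in% names(sp))
        stop("unknown species in config: ", nm)
      for (f in names(y$species[[nm]])) {
        if (!f %in% names(sp[[nm]])) stop("unknown species field: ", f)
        sp[[nm]][[f]] <- y$species[[nm]][[f]]
      }
    }
  }
  args <- y[intersect(names(y), c("seed", "n_trials", "permutation_runs",
                                  "feeding_from", "out_dir", "models"))]
  do.call(pipeline_config, c(list(species_params = sp), args))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, trait matching, transfer metrics, the trial-order
#' pre-check, the standard GLMMs, and the landscape resampling stage, and
#' writes every table (with provenance headers) plus a machine-readable
#' run manifest to the configured output directory.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with all in-memory results: `data` (simulated
#'   tables), `analysis`, `trial_effect`, `fits`, `models`,
#'   `permutations`, `landscape_summary`, `comparisons`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[pollenscape] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  say("stage simulate")
  data <- simulate_dataset(config$species_params, config$floral_params,
                           n_trials = config$n_trials, seed = seed)
  for (nm in c("birds", "flowers", "trials", "visits"))
    write_table(data[[nm]], file.path(config$out_dir, paste0(nm, ".csv")), seed)

  say("stage match + metrics")
  analysis <- assemble_analysis(data$trials, data$birds, data$flowers,
                                feeding_from = config$feeding_from)
  matching <- rbind(
    cbind(analysis$donor_matching,
          PC1 = analysis$donor_pca$scores[, 1],
          PC2 = analysis$donor_pca$scores[, 2],
          BL_SCO = NA_real_, BL_SN = NA_real_)[
            , c("bird_id", "species", "trial_number", "flower_id", "role",
                "BL_TCL", "BL_ECL", "BW_CW", "BL_ACO", "BL_AN", "BL_SCO",
                "BL_SN", "tarsus", "PC1", "PC2")],
    cbind(analysis$receiver_matching,
          PC1 = analysis$receiver_pca$scores[, 1],
          PC2 = analysis$receiver_pca$scores[, 2],
          BL_ACO = NA_real_, BL_AN = NA_real_)[
            , c("bird_id", "species", "trial_number", "flower_id", "role",
                "BL_TCL", "BL_ECL", "BW_CW", "BL_ACO", "BL_AN", "BL_SCO",
                "BL_SN", "tarsus", "PC1", "PC2")]
  )
  write_table(matching, file.path(config$out_dir, "matching.csv"), seed)
  write_table(analysis$metrics, file.path(config$out_dir, "metrics.csv"), seed)

  say("stage trial-order pre-check")
  tec <- trial_effect_check(data$trials)
  write_table(tec$table, file.path(config$out_dir, "trial_effect.csv"), seed)
  if (tec$include_trial)
    warning("trial-order effect detected; standard models omit the trial term")

  say("stage models")
  fits <- fit_standard_models(analysis, which = config$models)
  mtab <- models_table(fits)
  write_table(mtab, file.path(config$out_dir, "models.csv"), seed)

  say("stage landscape")
  pools <- deposition_pools(data$trials)
  runs <- run_permutations(data$visits, pools, R = config$permutation_runs,
                           seed = seed)
  lsum <- summarize_permutations(runs)
  comparisons <- list(
    mean_per_plant = compare_species(runs, "mean_per_plant"),
    landscape_total = compare_species(runs, "landscape_total"),
    flowers_probed = compare_species(metric = "flowers_probed",
                                     visits = data$visits)
  )
  write_table(runs, file.path(config$out_dir, "permutations.csv"), seed)
  write_table(lsum, file.path(config$out_dir, "landscape_summary.csv"), seed)

  manifest <- list(
    package = "pollenscape",
    version = as.character(utils::packageVersion("pollenscape")),
    seed = seed,
    n_trials = config$n_trials,
    permutation_runs = config$permutation_runs,
    models = config$models,
    feeding_from = config$feeding_from,
    species = names(config$species_params),
    n_birds = nrow(data$birds),
    n_trial_records = nrow(data$trials),
    n_visits = nrow(data$visits)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", config$out_dir)

  invisible(list(data = data, analysis = analysis, trial_effect = tec,
                 fits = fits, models = mtab, permutations = runs,
                 landscape_summary = lsum, comparisons = comparisons,
                 manifest = manifest))
}
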