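#' Convert high-speed-video frame counts to seconds
#'
#' @param frames Non-negative frame count(s).
#' @param fps Frame rate in frames per second (default 800, the filming
#'   rate used for the feeding trials).
#' @return `frames / fps`, in seconds.
#' @export
frames_to_seconds <- function(frames, fps = 800) {
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("`frames` must be non-negative")
  if (!is.numeric(fps) || fps <= 0) stop("`fps` must be positive")
  frames / fps
}

#' Parse a digitized polygon string
#'
#' Polygons are stored in CSV as `"x1 y1;x2 y2;..."` in pixel coordinates.
#' An empty string is an empty polygon (no pollen patch).
#'
#' @param s Character scalar.
#' @return Numeric matrix with columns `x`, `y` (0 rows for empty).
#' @export
parse_polygon <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  xy <- t(vapply(parts, function(p) {
    v <- as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    if (length(v) != 2L || anyNA(v)) stop("malformed polygon vertex: '", p, "'")
    v
  }, numeric(2)))
  dimnames(xy) <- list(NULL, c("x", "y"))
  xy
}

# Do segments p1-p2 and p3-p4 properly intersect (excluding shared endpoints)?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Area of a digitized pollen-patch polygon
#'
#' Shoelace (surveyor's) formula on the pixel coordinates, converted to
#' mm^2 with the image scale: `|signed px area| / scale^2`. The result is
#' independent of vertex orientation and of translation or rotation of the
#' image. Degenerate polygons (fewer than three vertices) have area 0. A
#' self-intersecting outline triggers a warning and returns the magnitude of
#' the signed area, which may under-represent the visible patch.
#'
#' @param vertices Two-column matrix of pixel coordinates, or a polygon
#'   string as accepted by [parse_polygon()].
#' @param scale Image scale in pixels per mm (> 0), set from known floral
#'   morphometrics in the same image.
#' @return Patch area in mm^2.
#' @export
polygon_area <- function(vertices, scale = 1) {
  if (is.character(vertices)) vertices <- parse_polygon(vertices)
  v <- as.matrix(vertices)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive pixels-per-mm value")
  n <- nrow(v)
  if (n < 3L) return(0)
  if (ncol(v) != 2L) stop("`vertices` must have two columns (x, y)")
  # self-intersection scan over non-adjacent edge pairs
  nxt <- c(seq_len(n)[-1], 1L)
  crossing <- FALSE
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next # adjacent through the closing edge
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        crossing <- TRUE
        break
      }
    }
    if (crossing) break
  }
  if (crossing)
    warning("self-intersecting polygon: returning |signed area|")
  x <- v[, 1]; y <- v[, 2]
  a_px <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  a_px / scale^2
}

#' Per-trial pollen-transfer and feeding-efficiency metrics
#'
#' Converts the raw video-derived measurements of a trials table into the
#' response variables of the downstream models: anther-contact duration (s),
#' pollen-patch area (mm^2), feeding-bout duration (s), feeding efficiency
#' (nectar volume consumed per second, microlitre/s) and licking rate
#' (licks/s). Frame counts are converted at the filming frame rate; patch
#' areas come from the digitized polygon and image scale; feeding efficiency
#' is the standardized nectar volume divided by the feeding-bout duration.
#'
#' @param trials Trials table (see [simulate_trials()] for the schema).
#' @param feeding_from Which visit's feeding bout defines the trial's
#'   primary feeding duration: `"receiver"` (default), `"donor"`, or
#'   `"pooled"` (mean of both). Donor- and receiver-specific durations and
#'   efficiencies are always returned alongside.
#' @param fps Frame rate (frames per second), default 800.
#' @return Data.frame with one row per trial: ids, `anther_contact_s`,
#'   `patch_area`, `feeding_duration_donor_s`, `feeding_duration_receiver_s`,
#'   `feeding_duration_s`, `feeding_efficiency_donor`,
#'   `feeding_efficiency_receiver`, `feeding_efficiency`, `licking_rate`.
#' @export
transfer_metrics <- function(trials, feeding_from = c("receiver", "donor", "pooled"),
                             fps = 800) {
  feeding_from <- match.arg(feeding_from)
  n <- nrow(trials)
  patch <- vapply(seq_len(n), function(i) {
    polygon_area(trials$patch_polygon[i], trials$image_scale[i])
  }, numeric(1))
  dur_d <- frames_to_seconds(trials$feeding_frames_donor, fps)
  dur_r <- frames_to_seconds(trials$feeding_frames_receiver, fps)
  dur <- switch(feeding_from,
                receiver = dur_r, donor = dur_d, pooled = (dur_d + dur_r) / 2)
  if (any(dur <= 0 & trials$lick_count > 0))
    stop("zero feeding duration with nonzero lick count: inconsistent record(s) ",
         paste(which(dur <= 0 & trials$lick_count > 0), collapse = ", "))
  vol <- trials$nectar_volume
  eff <- ifelse(dur > 0, vol / dur, NA_real_)
  data.frame(
    bird_id = trials$bird_id,
    species = trials$species,
    trial_number = trials$trial_number,
    anther_contact_s = frames_to_seconds(trials$anther_contact_frames, fps),
    patch_area = patch,
    feeding_duration_donor_s = dur_d,
    feeding_duration_receiver_s = dur_r,
    feeding_duration_s = dur,
    feeding_efficiency_donor = ifelse(dur_d > 0, vol / dur_d, NA_real_),
    feeding_efficiency_receiver = ifelse(dur_r > 0, vol / dur_r, NA_real_),
    feeding_efficiency = eff,
    licking_rate = ifelse(dur > 0, trials$lick_count / dur, 0),
    stringsAsFactors = FALSE
  )
}

#' Per-species summary of transfer and feeding metrics
#'
#' Mean and standard error per species for each numeric metric. The SE is
#' SD / sqrt(n) with n the number of trials (trial-level replication, as in
#' per-trial violin plots); set `by_bird = TRUE` to aggregate to bird means
#' first.
#'
#' @param metrics Output of [transfer_metrics()].
#' @param by_bird Aggregate to per-bird means before summarizing?
#' @return Long data.frame: `species`, `metric`, `n`, `mean`, `se`.
#' @export
species_summary <- function(metrics, by_bird = FALSE) {
  vars <- c("anther_contact_s", "patch_area", "feeding_duration_s",
            "feeding_efficiency", "licking_rate")
  vars <- intersect(vars, names(metrics))
  if (by_bird) {
    agg <- stats::aggregate(metrics[vars],
                            by = list(species = metrics$species,
                                      bird_id = metrics$bird_id),
                            FUN = mean, na.rm = TRUE)
    metrics <- agg
  }
  out <- lapply(vars, function(v) {
    x <- split(metrics[[v]], metrics$species)
    data.frame(
      species = names(x),
      metric = v,
      n = vapply(x, function(z) sum(!is.na(z)), integer(1)),
      mean = vapply(x, function(z) mean(z, na.rm = TRUE), numeric(1)),
      se = vapply(x, function(z) {
        z <- z[!is.na(z)]
        stats::sd(z) / sqrt(length(z))
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
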