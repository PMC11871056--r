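#' Bill-corolla matching ratios for one bird-flower pair
#'
#' Each matching metric is a bird bill measurement divided by a floral
#' measurement; a value of 1 means the two structures are the same size,
#' values below 1 a flower larger than the bill, values above 1 a bill
#' larger than the flower. Donor flowers (anthers intact) yield the
#' anther-distance ratios BL/ACO and BL/AN; receiver flowers (stigma only)
#' yield the stigma-distance ratios BL/SCO and BL/SN. Tarsus length is
#' carried through unchanged to account for body size in the multivariate
#' analysis.
#'
#' @param bird One-row data.frame (or list) with `bill_length`, `bill_width`
#'   and `tarsus`.
#' @param flower One-row data.frame (or list) with `role` ("donor" or
#'   "receiver"), `TCL`, `ECL`, `CW` and the role-appropriate `ACO`/`AN` or
#'   `SCO`/`SN`.
#' @return One-row data.frame of ratios: `BL_TCL`, `BL_ECL`, `BW_CW`, plus
#'   `BL_ACO`/`BL_AN` (donor) or `BL_SCO`/`BL_SN` (receiver), and `tarsus`.
#' @export
compute_ratios <- function(bird, flower) {
  role <- as.character(flower$role)
  if (!role %in% c("donor", "receiver"))
    stop("flower `role` must be 'donor' or 'receiver'")
  num <- function(v, nm) {
    x <- as.numeric(v)
    if (length(x) != 1L || is.na(x))
      stop("measurement `", nm, "` is missing")
    x
  }
  den <- function(v, nm) {
    x <- num(v, nm)
    if (x <= 0) stop("floral measurement `", nm, "` must be positive to form a ratio")
    x
  }
  bl <- num(bird$bill_length, "bill_length")
  bw <- num(bird$bill_width, "bill_width")
  out <- data.frame(
    BL_TCL = bl / den(flower$TCL, "TCL"),
    BL_ECL = bl / den(flower$ECL, "ECL"),
    BW_CW = bw / den(flower$CW, "CW")
  )
  if (role == "donor") {
    out$BL_ACO <- bl / den(flower$ACO, "ACO")
    out$BL_AN <- bl / den(flower$AN, "AN")
  } else {
    out$BL_SCO <- bl / den(flower$SCO, "SCO")
    out$BL_SN <- bl / den(flower$SN, "SN")
  }
  out$tarsus <- num(bird$tarsus, "tarsus")
  out
}

# Role-specific variable sets entering the PCAs.
matching_variables <- function(role) {
  shared <- c("BL_TCL", "BL_ECL", "BW_CW")
  if (role == "donor") c(shared, "BL_ACO", "BL_AN", "tarsus")
  else c(shared, "BL_SCO", "BL_SN", "tarsus")
}

#' Matching-ratio table for all trial visits of one role
#'
#' Joins the trials table to bird and flower morphometrics and computes one
#' row of matching ratios per trial visit of the requested role.
#'
#' @param trials,birds,flowers Tables as produced by [simulate_dataset()]
#'   (or read from the corresponding CSV files).
#' @param role `"donor"` or `"receiver"`.
#' @return Data.frame with `bird_id`, `species`, `trial_number`,
#'   `flower_id`, `role` and the role's matching ratios.
#' @export
matching_table <- function(trials, birds, flowers, role = c("donor", "receiver")) {
  role <- match.arg(role)
  id_col <- paste0(role, "_flower_id")
  fl <- flowers[match(trials[[id_col]], flowers$flower_id), , drop = FALSE]
  if (anyNA(fl$flower_id))
    stop("trials reference ", role, " flowers absent from the flowers table")
  bd <- birds[match(trials$bird_id, birds$bird_id), , drop = FALSE]
  if (anyNA(bd$bird_id))
    stop("trials reference birds absent from the birds table")
  rat <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    compute_ratios(bd[i, ], fl[i, ])
  }))
  cbind(
    data.frame(bird_id = trials$bird_id, species = trials$species,
               trial_number = trials$trial_number,
               flower_id = fl$flower_id, role = role,
               stringsAsFactors = FALSE),
    rat
  )
}

#' Principal component analysis of matching ratios
#'
#' PCA of the correlation matrix: variables are centred and scaled to unit
#' (n-1) standard deviation before eigendecomposition, so the result is
#' invariant to affine rescaling of any input column. Components are ordered
#' by decreasing explained variance, and each component's sign is fixed so
#' that its largest-magnitude loading is positive (PCA signs are otherwise
#' arbitrary; downstream models use absolute scores so results do not depend
#' on this convention, but plots and tests need determinism).
#'
#' @param x Data.frame or matrix of observations x variables, no missing
#'   values, every column with nonzero variance.
#' @return An object of class `matching_pca`: list with `loadings`
#'   (variables x components), `scores` (observations x components),
#'   `variance_fraction`, `center_vector`, `scale_vector`,
#'   `variable_names`.
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("PCA input must be numeric")
  if (nrow(x) < 2L) stop("PCA needs at least two observations")
  if (anyNA(x)) stop("PCA input has missing cells")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- p$rotation
  scores <- p$x
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    loadings = load,
    scores = scores,
    variance_fraction = p$sdev^2 / sum(p$sdev^2),
    center_vector = p$center,
    scale_vector = p$scale,
    variable_names = colnames(x)
  ), class = "matching_pca")
}

#' @export
print.matching_pca <- function(x, ...) {
  cat("Matching-ratio PCA:", length(x$variable_names), "variables,",
      nrow(x$scores), "observations\n")
  vf <- round(100 * x$variance_fraction, 1)
  cat("Variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Absolute-value matching scores
#'
#' Converts signed PC scores to magnitudes: zero is the closest
#' bill-corolla match (the multivariate centroid) and larger values are
#' more mismatched in either direction (bill larger or smaller than the
#' flower).
#'
#' @param pc A `matching_pca` object from [run_pca()].
#' @param components Integer vector of component indices (default first two).
#' @return Matrix of `|score|` values, columns named `abs_PC<k>`.
#' @export
abs_scores <- function(pc, components = 1:2) {
  stopifnot(inherits(pc, "matching_pca"))
  if (any(components < 1 | components > ncol(pc$scores)))
    stop("requested components do not exist")
  out <- abs(pc$scores[, components, drop = FALSE])
  colnames(out) <- paste0("abs_PC", components)
  out
}
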