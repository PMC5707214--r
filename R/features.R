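occipital_mean <- function(volume) {
  if (!any(volume$masks$occipital)) stop_invalid_geometry("occipital mask is empty")
  mean(volume$intensities[volume$masks$occipital])
}

#' Regional striatal binding ratio from a volume
#'
#' The SBR of a target region is its specific uptake relative to the
#' non-specific occipital reference:
#' `(mean(target) - mean(occipital)) / mean(occipital)`. The ratio is
#' invariant under global rescaling of the volume.
#'
#' @param volume A `phantom_volume`.
#' @param region One of `"l_putamen"`, `"r_putamen"`, `"l_caudate"`,
#'   `"r_caudate"` (any named mask is accepted).
#' @return The SBR as a plain number.
#' @export
compute_sbr <- function(volume, region) {
  m <- volume$masks[[region]]
  if (is.null(m)) stop_configuration(paste("no mask named", region))
  if (!any(m)) stop_invalid_geometry(paste("mask", region, "is empty"))
  occ <- occipital_mean(volume)
  if (occ <= 0) stop_degenerate_reference("occipital mean must be > 0")
  (mean(volume$intensities[m]) - occ) / occ
}

#' Scale a volume to its occipital mean
#'
#' Divides every voxel by the occipital ROI mean, removing global intensity
#' variation; the occipital mean of the result is exactly 1. Idempotent.
#'
#' @param volume A `phantom_volume`.
#' @return The rescaled `phantom_volume`.
#' @export
scale_to_occipital <- function(volume) {
  occ <- occipital_mean(volume)
  if (occ <= 0) stop_degenerate_reference("occipital mean must be > 0")
  volume$intensities <- volume$intensities / occ
  volume
}

#' Orient the most diseased striatum to the left
#'
#' If the summed uptake over the left putamen and caudate exceeds the
#' right-side sum, the volume is mirrored about the central sagittal plane and
#' the left/right masks are swapped, so the lower-uptake (more diseased)
#' striatum always ends up on the left. A tie leaves the volume unchanged.
#'
#' @param volume A `phantom_volume` with a mirror-symmetric mask layout.
#' @return A list with elements `volume` and `flipped` (logical flag).
#' @export
flip_if_needed <- function(volume) {
  m <- volume$masks
  for (r in c("l_putamen", "l_caudate"))
    if (!any(m[[r]]) || !any(m[[sub("^l_", "r_", r)]]))
      stop_invalid_geometry("both striatal sides must have non-empty masks")
  if (!identical(mirror_array(m$l_putamen), m$r_putamen) ||
      !identical(mirror_array(m$l_caudate), m$r_caudate))
    stop_invalid_geometry("masks are not mirror images; cannot flip")
  left  <- sum(volume$intensities[m$l_putamen | m$l_caudate])
  right <- sum(volume$intensities[m$r_putamen | m$r_caudate])
  if (left <= right) return(list(volume = volume, flipped = FALSE))
  volume$intensities <- mirror_array(volume$intensities)
  volume$masks <- lapply(volume$masks, mirror_array)
  nm <- names(volume$masks)
  swapped <- nm
  swapped[grepl("^l_", nm)] <- sub("^l_", "r_", nm[grepl("^l_", nm)])
  swapped[grepl("^r_", nm)] <- sub("^r_", "l_", nm[grepl("^r_", nm)])
  names(volume$masks) <- swapped
  volume$masks <- volume$masks[nm]
  list(volume = volume, flipped = TRUE)
}

#' Build a feature set for the classification pipelines
#'
#' Three feature families are supported, mirroring the SVM pipelines:
#' \describe{
#'   \item{`"sbrs"`}{the four regional SBRs straight from the cohort table,
#'     plus age — no volumes needed.}
#'   \item{`"voxels"`}{each subject's volume is flipped so the most diseased
#'     striatum is on the left, scaled to its occipital mean, and the voxels
#'     inside the loose striatal mask are taken in a fixed template order,
#'     plus age.}
#'   \item{`"pcs"`}{the same voxel matrix, tagged for principal-component
#'     projection; the PCA itself is fitted per training fold downstream so no
#'     test information leaks into the components.}
#' }
#' Age is appended as the last column of every family and is standardized like
#' any other feature by the downstream pipeline.
#'
#' @param cohort A cohort data frame.
#' @param volumes For the voxel families: a list of `phantom_volume`s, either
#'   named by subject id or in cohort order.
#' @param kind `"sbrs"`, `"voxels"` or `"pcs"`.
#' @param n_components Number of components recorded for `kind = "pcs"`.
#' @return A `feature_set`: list with `matrix` (subjects x features), `kind`,
#'   `n_components`, `age_col` (index of the age column) and `feature_names`.
#' @export
extract_features <- function(cohort, volumes = NULL,
                             kind = c("sbrs", "voxels", "pcs"),
                             n_components = NULL) {
  kind <- match.arg(kind)
  validate_cohort(cohort)
  if (kind == "sbrs") {
    mat <- cbind(as.matrix(cohort[SBR_COLUMNS]), age = cohort$age)
  } else {
    if (is.null(volumes)) stop_missing_input("voxel features require volumes")
    if (!is.null(names(volumes))) {
      miss <- setdiff(cohort$id, names(volumes))
      if (length(miss))
        stop_missing_input(paste("no volume for subject(s):", paste(miss, collapse = ", ")))
      volumes <- volumes[cohort$id]
    } else if (length(volumes) != nrow(cohort)) {
      stop_missing_input("unnamed volume list must match cohort length and order")
    }
    rows <- lapply(volumes, function(v) {
      v <- flip_if_needed(v)$volume
      v <- scale_to_occipital(v)
      v$intensities[v$masks$striatal_loose]
    })
    nv <- lengths(rows)
    if (length(unique(nv)) != 1L)
      stop_invalid_geometry("all volumes must share the same loose striatal mask size")
    mat <- cbind(do.call(rbind, rows), age = cohort$age)
    colnames(mat) <- c(paste0("vox", seq_len(nv[1])), "age")
  }
  rownames(mat) <- cohort$id
  structure(
    list(matrix = mat, kind = kind,
         n_components = if (kind == "pcs") n_components else NULL,
         age_col = ncol(mat), feature_names = colnames(mat)),
    class = "feature_set"
  )
}
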