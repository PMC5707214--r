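STRIATAL_REGIONS <- c("l_putamen", "r_putamen", "l_caudate", "r_caudate")
ALL_REGIONS <- c(STRIATAL_REGIONS, "occipital", "striatal_loose")

# region name -> cohort SBR column
region_to_column <- function(region) paste0("sbr_", region)

mirror_array <- function(a) {
  d <- dim(a)
  a[d[1]:1, , , drop = FALSE]
}

ellipsoid_mask <- function(dim3, centre, radii) {
  x <- seq_len(dim3[1]); y <- seq_len(dim3[2]); z <- seq_len(dim3[3])
  dx2 <- ((x - centre[1]) / radii[1])^2
  dy2 <- ((y - centre[2]) / radii[2])^2
  dz2 <- ((z - centre[3]) / radii[3])^2
  array(outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1, dim = dim3)
}

# exponent-4 superellipsoid: boxier than an ellipsoid, hugs the striatal span
superellipsoid_mask <- function(dim3, centre, radii, p = 4) {
  x <- seq_len(dim3[1]); y <- seq_len(dim3[2]); z <- seq_len(dim3[3])
  dx <- abs((x - centre[1]) / radii[1])^p
  dy <- abs((y - centre[2]) / radii[2])^p
  dz <- abs((z - centre[3]) / radii[3])^p
  array(outer(outer(dx, dy, `+`), dz, `+`) <= 1, dim = dim3)
}

box_mask <- function(dim3, xr, yr, zr) {
  m <- array(FALSE, dim = dim3)
  m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  m
}

#' Phantom geometry in template space
#'
#' Builds the fixed ROI layout used by the volume generator: ellipsoidal
#' left/right putamen and caudate pairs near the grid centre, a cuboid
#' occipital reference region posteriorly, and a loose ellipsoidal striatal
#' mask enclosing all four striatal ROIs. The first array axis runs
#' left-to-right (left = low index), the second anterior-to-posterior, the
#' third inferior-to-superior. All ROIs are mirror-symmetric about the central
#' sagittal plane so volumes can be flipped without resampling. Sizes scale
#' linearly with `dim`.
#'
#' @param dim Cubic grid size in voxels (default 64).
#' @param voxel_size Isotropic voxel edge in mm.
#' @param background Non-specific (occipital) activity level in arbitrary
#'   counts.
#' @return A `phantom_geometry` object: grid metadata plus a named list of
#'   logical mask arrays.
#' @export
phantom_geometry <- function(dim = 64L, voxel_size = 2, background = 20) {
  dim <- as.integer(dim)
  if (dim < 16L) stop_invalid_parameter("grid dimension must be >= 16")
  if (background <= 0) stop_invalid_parameter("background must be > 0")
  s <- dim / 64
  d3 <- rep(dim, 3L)
  mid <- (dim + 1) / 2  # mirror axis: index i <-> dim + 1 - i
  lp_c <- c(21, 30, 32) * s; lp_r <- c(3.5, 5.5, 4.5) * s
  lc_c <- c(27, 20, 34) * s; lc_r <- c(2.5, 3.5, 3.0) * s
  masks <- list(
    l_putamen = ellipsoid_mask(d3, lp_c, lp_r),
    r_putamen = ellipsoid_mask(d3, c(dim + 1 - lp_c[1], lp_c[2], lp_c[3]), lp_r),
    l_caudate = ellipsoid_mask(d3, lc_c, lc_r),
    r_caudate = ellipsoid_mask(d3, c(dim + 1 - lc_c[1], lc_c[2], lc_c[3]), lc_r),
    occipital = box_mask(d3, round(c(24 * s, dim + 1 - 24 * s)),
                         round(c(50 * s, 58 * s)), round(c(28 * s, 36 * s))),
    striatal_loose = superellipsoid_mask(d3, c(mid, 26 * s, 32.5 * s),
                                         c(16.5, 11, 6.5) * s)
  )
  geom <- structure(
    list(dim = d3, voxel_size = voxel_size, background = background, masks = masks),
    class = "phantom_geometry"
  )
  validate_geometry(geom)
  geom
}

#' Validate mask layout invariants
#'
#' Checks that the four striatal masks and the occipital mask are pairwise
#' disjoint, that the loose striatal mask contains every striatal mask and is
#' disjoint from the occipital mask, and that the layout is mirror-symmetric
#' about the central sagittal plane.
#'
#' @param geom A `phantom_geometry` or any list with a compatible `masks`
#'   entry.
#' @return The geometry, invisibly; classed error on violation.
#' @export
validate_geometry <- function(geom) {
  m <- geom$masks
  if (!all(ALL_REGIONS %in% names(m)))
    stop_invalid_geometry(paste("masks must include:", paste(ALL_REGIONS, collapse = ", ")))
  if (!all(vapply(m, any, logical(1))))
    stop_invalid_geometry("every mask must contain at least one voxel")
  core <- c(STRIATAL_REGIONS, "occipital")
  for (i in seq_along(core)) for (j in seq_len(i - 1L)) {
    if (any(m[[core[i]]] & m[[core[j]]]))
      stop_invalid_geometry(sprintf("masks %s and %s overlap", core[i], core[j]))
  }
  for (r in STRIATAL_REGIONS) {
    if (any(m[[r]] & !m$striatal_loose))
      stop_invalid_geometry(sprintf("striatal_loose does not contain %s", r))
  }
  if (any(m$occipital & m$striatal_loose))
    stop_invalid_geometry("occipital mask overlaps striatal_loose")
  if (!identical(mirror_array(m$l_putamen), m$r_putamen) ||
      !identical(mirror_array(m$l_caudate), m$r_caudate) ||
      !identical(mirror_array(m$occipital), m$occipital) ||
      !identical(mirror_array(m$striatal_loose), m$striatal_loose))
    stop_invalid_geometry("mask layout is not mirror-symmetric about the sagittal plane")
  invisible(geom)
}

#' Synthesise a phantom volume for one subject
#'
#' Constructs a template-space activity grid whose regional contrasts encode
#' the subject's SBRs exactly: every voxel starts at the background level `B`
#' and each striatal ROI is set to `B * (1 + SBR)`, so that
#' `(ROI mean - occipital mean) / occipital mean` recovers the SBR before
#' noise. Independent Gaussian noise with SD `noise_sd * B` is then added and
#' intensities are truncated at zero. Registration is assumed perfect: all
#' subjects share the template ROI layout.
#'
#' @param record One cohort row (a list or single-row data frame with the four
#'   `sbr_*` columns).
#' @param geometry A `phantom_geometry`.
#' @param noise_sd Voxel noise SD as a fraction of the background level.
#' @param seed Integer seed; same record, geometry and seed give a
#'   bit-identical volume.
#' @return A `phantom_volume`: intensities array, voxel size and the named
#'   mask list.
#' @export
generate_volume <- function(record, geometry, noise_sd = 0.05, seed = 1L) {
  validate_geometry(geometry)
  if (noise_sd < 0) stop_invalid_parameter("noise_sd must be >= 0")
  sbrs <- vapply(region_to_column(STRIATAL_REGIONS),
                 function(cn) as.numeric(record[[cn]]), numeric(1))
  names(sbrs) <- STRIATAL_REGIONS
  if (any(!is.finite(sbrs)) || any(sbrs <= 0))
    stop_invalid_input("record must carry four positive SBRs")
  b <- geometry$background
  vol <- array(b, dim = geometry$dim)
  for (r in STRIATAL_REGIONS) vol[geometry$masks[[r]]] <- b * (1 + sbrs[[r]])
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vol <- pmax(vol + array(stats::rnorm(length(vol), 0, noise_sd * b),
                            dim = geometry$dim), 0)
  }
  structure(
    list(intensities = vol, voxel_size = geometry$voxel_size,
         masks = geometry$masks),
    class = "phantom_volume"
  )
}

mask_bits <- stats::setNames(2L^(0:5), ALL_REGIONS)

#' Write/read a phantom volume as NIfTI-1 plus a JSON mask sidecar
#'
#' `write_phantom` writes `<prefix>.nii.gz` (intensities),
#' `<prefix>_masks.nii.gz` (an integer bit-flag label map; masks may overlap,
#' each occupies one bit) and `<prefix>_masks.json` naming the bit value of
#' each region. `read_phantom` reverses the operation.
#'
#' @param volume A `phantom_volume`.
#' @param prefix Path prefix without extension.
#' @return `write_phantom` returns `prefix` invisibly; `read_phantom` a
#'   `phantom_volume`.
#' @export
write_phantom <- function(volume, prefix) {
  hdr <- list(pixdim = c(-1, rep(volume$voxel_size, 3), 0, 0, 0, 0))
  RNifti::writeNifti(RNifti::asNifti(volume$intensities, reference = hdr),
                     paste0(prefix, ".nii.gz"))
  lab <- array(0L, dim = dim(volume$intensities))
  for (r in names(volume$masks)) lab[volume$masks[[r]]] <- lab[volume$masks[[r]]] + mask_bits[[r]]
  RNifti::writeNifti(RNifti::asNifti(lab, reference = hdr, datatype = "int32"),
                     paste0(prefix, "_masks.nii.gz"))
  jsonlite::write_json(as.list(mask_bits), paste0(prefix, "_masks.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  lab <- RNifti::readNifti(paste0(prefix, "_masks.nii.gz"))
  bits <- jsonlite::read_json(paste0(prefix, "_masks.json"), simplifyVector = TRUE)
  lab_i <- array(as.integer(round(lab)), dim = dim(lab))
  masks <- lapply(bits, function(b) array(bitwAnd(lab_i, as.integer(b)) > 0L, dim = dim(lab_i)))
  structure(
    list(intensities = array(as.numeric(img), dim = dim(img)),
         voxel_size = RNifti::pixdim(img)[1], masks = masks),
    class = "phantom_volume"
  )
}
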