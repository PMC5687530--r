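#' Lung lobe and airway-region vocabularies
#'
#' Fixed label sets used throughout the package: the five lung lobes
#' (left/right upper, right middle, left/right lower) and the ten named
#' airway regions — five central airways (trachea, right and left main
#' bronchi, right intermediate bronchus, trifurcation of the left lower
#' lobe) and five subgrouped segmental regions, one per lobe.
#'
#' @return A character vector of labels.
#' @export
#' @examples
#' lobe_labels()
#' airway_regions()
lobe_labels <- function() c("LUL", "LLL", "RUL", "RML", "RLL")

#' @rdname lobe_labels
#' @export
airway_regions <- function() {
  c("trachea", "RMB", "LMB", "BronInt", "TriLLB",
    "sLUL", "sRUL", "sRML", "sLLL", "sRLL")
}

#' Create an image volume
#'
#' A minimal carrier for a 3-D scalar grid (CT attenuation in HU, or a
#' derived fraction map) with isotropic or anisotropic voxel spacing in mm.
#'
#' @param data A numeric 3-D array.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm.
#' @return An object of class `qct_volume`.
#' @export
#' @examples
#' v <- qct_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1.5))
#' dim(v)
qct_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  structure(list(data = data, spacing = spacing), class = "qct_volume")
}

#' @export
dim.qct_volume <- function(x) dim(x$data)

#' @export
print.qct_volume <- function(x, ...) {
  cat("<qct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  range: [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' Create a displacement field
#'
#' Per-voxel 3-vector displacements u(x) in mm on the expiration grid. The
#' convention throughout the package is that the field maps an
#' expiration-grid point x (world mm) to its inspiration-space position
#' x + u(x).
#'
#' @param data A numeric 4-D array with last dimension 3 (displacement
#'   components in mm, ordered as the grid axes).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `qct_field`.
#' @export
qct_field <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 3L) {
    abort("`data` must be a 4-D array with 3 components in the last dimension.")
  }
  if (any(!is.finite(data))) abort("Displacement field must be finite everywhere.")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  structure(list(data = data, spacing = spacing), class = "qct_field")
}

#' @export
dim.qct_field <- function(x) dim(x$data)[1:3]

#' @export
print.qct_field <- function(x, ...) {
  mag <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat("<qct_field> ", paste(dim(x), collapse = " x "),
      " voxels, |u| up to ", format(max(mag), digits = 4), " mm\n", sep = "")
  invisible(x)
}

#' Create a lobe label mask
#'
#' Integer label grid aligned to an image volume: 0 outside the lung,
#' 1..5 for the lobes in the order of [lobe_labels()].
#'
#' @param data Integer-valued 3-D array with values in 0..5.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `qct_lobe_mask`.
#' @export
qct_lobe_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array of lobe labels.")
  }
  vals <- unique(as.vector(data))
  if (any(!vals %in% 0:5)) {
    abort("Lobe mask values must be integers 0 (outside lung) to 5.")
  }
  v <- qct_volume(array(as.integer(data), dim(data)), spacing)
  class(v) <- c("qct_lobe_mask", class(v))
  v
}

as_array <- function(x) {
  if (inherits(x, "qct_volume") || inherits(x, "qct_field")) x$data else x
}

check_aligned <- function(..., what = "inputs") {
  objs <- list(...)
  dims <- lapply(objs, function(o) dim(as_array(o))[1:3])
  sp <- lapply(objs, function(o) if (is.list(o) && !is.null(o$spacing)) o$spacing else NULL)
  ref <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, ref), logical(1)))) {
    abort(paste0("Grid mismatch: ", what, " must share the same voxel dimensions."))
  }
  sp <- sp[!vapply(sp, is.null, logical(1))]
  if (length(sp) > 1) {
    refs <- sp[[1]]
    if (!all(vapply(sp, function(s) isTRUE(all.equal(s, refs)), logical(1)))) {
      abort(paste0("Spacing mismatch: ", what, " must share voxel spacing."))
    }
  }
  invisible(TRUE)
}

# Logical array that is TRUE strictly inside the grid (one-voxel shell
# removed), where central-difference stencils apply.
interior_mask <- function(dm) {
  m <- array(FALSE, dm)
  m[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)] <- TRUE
  m
}

#' Summarise a voxel map over lung lobes
#'
#' Means of a scalar field over each lobe and over the whole lung, as a
#' tibble. Optionally restricts to interior voxels (one-voxel shell of the
#' grid removed) and to an additional validity mask, so that boundary
#' finite-difference stencils or out-of-domain warps never bias a lobar
#' summary.
#'
#' @param volume A [qct_volume()] (or bare 3-D array) of per-voxel values.
#' @param lobe_mask A [qct_lobe_mask()] aligned to `volume`.
#' @param exclude_boundary Drop the one-voxel outer shell of the grid
#'   (default `FALSE`).
#' @param valid Optional logical array marking voxels eligible for the
#'   summary (e.g. the validity mask of a warped map).
#' @param value_name Column name for the summarised value.
#' @return A tibble with one row per lobe plus a `"whole"` row: region,
#'   number of voxels used, and the mean value.
#' @export
lobar_means <- function(volume, lobe_mask, exclude_boundary = FALSE,
                        valid = NULL, value_name = "value") {
  check_aligned(volume, lobe_mask, what = "volume and lobe mask")
  v <- as_array(volume)
  lab <- as_array(lobe_mask)
  keep <- lab > 0L
  if (exclude_boundary) keep <- keep & interior_mask(dim(v))
  if (!is.null(valid)) keep <- keep & valid
  res <- purrr::map_dfr(seq_along(lobe_labels()), function(l) {
    sel <- keep & lab == l
    n <- sum(sel)
    tibble(region = lobe_labels()[l], n_voxels = n,
           value = if (n > 0) mean(v[sel]) else NA_real_)
  })
  whole <- tibble(region = "whole", n_voxels = sum(keep),
                  value = if (any(keep)) mean(v[keep]) else NA_real_)
  out <- dplyr::bind_rows(res, whole)
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving voxel data bit-exactly and mm
#' spacing within float32 representation. Scalar volumes are 3-D; vector
#' displacement fields are stored as 4-D images with three components.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param volume A [qct_volume()], [qct_lobe_mask()] or [qct_field()].
#' @return `read_volume()` returns a [qct_volume()] (or [qct_field()] for
#'   3-component 4-D payloads); `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  sp <- RNifti::pixdim(img)
  if (length(dm) == 3L) {
    qct_volume(array(as.double(img), dm), spacing = as.double(sp[1:3]))
  } else if (length(dm) == 4L && dm[4] == 3L) {
    qct_field(array(as.double(img), dm), spacing = as.double(sp[1:3]))
  } else {
    abort("NIfTI payload must be a 3-D scalar volume or a 3-component 4-D field.")
  }
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  if (!(inherits(volume, "qct_volume") || inherits(volume, "qct_field"))) {
    abort("`volume` must be a qct_volume, qct_lobe_mask or qct_field.")
  }
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- if (inherits(volume, "qct_field")) {
    c(volume$spacing, 1)
  } else {
    volume$spacing
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
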