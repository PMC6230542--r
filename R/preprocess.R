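#' Preprocessing configuration
#'
#' The exact input conditioning applied before network training: intensity
#' scaling of PET by 6000 Bq/ml and of CT by 2000 HU (after a +1000 HU offset
#' that maps the air floor to zero), a minimal bounding-box crop around the
#' imaged object, slice-wise bilinear resampling to the target matrix, and a
#' pixel-wise Softsign transform. All steps are invertible, and the inverse
#' chain maps network output back to Hounsfield units.
#'
#' @param pet_scale PET normalization constant, Bq/ml
#' @param ct_scale CT normalization constant, HU
#' @param ct_offset HU added before scaling (maps -1000 HU air to 0)
#' @param target_matrix network matrix size (rows, cols)
#' @param crop_threshold foreground threshold as a fraction of the slice max
#' @param crop_margin margin in pixels added around the bounding box
#' @export
preprocess_config <- function(pet_scale = 6000, ct_scale = 2000,
                              ct_offset = 1000, target_matrix = c(200L, 180L),
                              crop_threshold = 0.01, crop_margin = 2L) {
  stopifnot(pet_scale > 0, ct_scale > 0, all(target_matrix >= 8))
  structure(list(pet_scale = pet_scale, ct_scale = ct_scale,
                 ct_offset = ct_offset,
                 target_matrix = as.integer(target_matrix),
                 crop_threshold = crop_threshold,
                 crop_margin = as.integer(crop_margin)),
            class = "preprocess_config")
}

#' Normalize PET intensities
#'
#' Reconstructed PET is non-negative, so no offset is applied; values are
#' divided by the PET scale (6000 Bq/ml maps to 1).
#' @param pet a \code{pet_image} or numeric array, Bq/ml
#' @param cfg a \code{\link{preprocess_config}}
#' @export
normalize_pet <- function(pet, cfg = preprocess_config()) {
  v <- if (inherits(pet, "pet_image")) pet$voxels else pet
  if (any(v < 0)) stop("NAC PET input must be non-negative")
  v / cfg$pet_scale
}

#' Normalize CT to the network domain, and back
#'
#' Forward: \eqn{(HU + offset) / scale}. \code{rescale_to_hu} is the exact
#' inverse (applied to network output after Softsign inversion).
#' @param ct a \code{ct_volume} or numeric array of HU
#' @param cfg a \code{\link{preprocess_config}}
#' @export
normalize_ct <- function(ct, cfg = preprocess_config()) {
  v <- if (inherits(ct, "ct_volume")) ct$voxels else ct
  stopifnot(all(is.finite(v)))
  (v + cfg$ct_offset) / cfg$ct_scale
}

#' @rdname normalize_ct
#' @param pred normalized prediction (after Softsign inversion)
#' @export
rescale_to_hu <- function(pred, cfg = preprocess_config()) {
  pred * cfg$ct_scale - cfg$ct_offset
}

#' Softsign transform and its inverse
#'
#' \eqn{y = x / (1 + |x|)} compresses values into (-1, 1); the inverse
#' \eqn{x = y / (1 - |y|)} is exact on that range. Both are elementwise,
#' sign-preserving, and strictly monotone.
#' @param x numeric array
#' @export
softsign <- function(x) x / (1 + abs(x))

#' @rdname softsign
#' @param y numeric array with \code{|y| < 1}
#' @export
inverse_softsign <- function(y) {
  if (any(abs(y) >= 1)) stop("inverse_softsign: |y| >= 1 is outside the range")
  y / (1 - abs(y))
}

#' Minimal bounding box around the imaged object
#'
#' Per slice, foreground is every pixel strictly above
#' \code{crop_threshold * max(slice)}; the returned box is the union over
#' slices (all slices share one box, preserving inter-slice geometry),
#' expanded by \code{crop_margin} and clipped to the volume bounds.
#' Coordinates are 0-based half-open \code{(row0, col0, row1, col1)}.
#'
#' @param volume 3D array (rows, cols, slices) or 2D array
#' @param cfg a \code{\link{preprocess_config}}
#' @return list with \code{cropped} and \code{crop_box}
#' @export
crop_bounding_box <- function(volume, cfg = preprocess_config()) {
  v <- if (length(dim(volume)) == 2) array(volume, c(dim(volume), 1)) else volume
  rows <- logical(dim(v)[1]); cols <- logical(dim(v)[2])
  for (s in seq_len(dim(v)[3])) {
    sl <- v[, , s]
    thr <- cfg$crop_threshold * max(sl)
    fg <- sl > thr
    rows <- rows | apply(fg, 1, any)
    cols <- cols | apply(fg, 2, any)
  }
  if (!any(rows))
    stop("empty foreground at crop_threshold = ", cfg$crop_threshold,
         "; lower the threshold")
  r <- range(which(rows)); c <- range(which(cols))
  r0 <- max(1L, r[1] - cfg$crop_margin); r1 <- min(dim(v)[1], r[2] + cfg$crop_margin)
  c0 <- max(1L, c[1] - cfg$crop_margin); c1 <- min(dim(v)[2], c[2] + cfg$crop_margin)
  cropped <- v[r0:r1, c0:c1, , drop = FALSE]
  if (length(dim(volume)) == 2) cropped <- cropped[, , 1]
  list(cropped = cropped, crop_box = c(r0 - 1L, c0 - 1L, r1, c1))
}

#' Bilinear resampling of a 2D slice
#'
#' Corner-aligned sampling: output pixel i (0-based) samples the source at
#' \eqn{i (S-1)/(T-1)}. A target equal to the source shape is the identity.
#' @param slice 2D array
#' @param target integer pair (rows, cols), each >= 2
#' @export
resample_bilinear <- function(slice, target) {
  stopifnot(all(target >= 2))
  src <- dim(slice)
  if (all(src == target)) return(slice)
  interp_matrix <- function(S, T) {
    pos <- (0:(T - 1)) * (S - 1) / (T - 1)
    i0 <- pmin(floor(pos), S - 2)
    f <- pos - i0
    A <- matrix(0, T, S)
    A[cbind(1:T, i0 + 1)] <- 1 - f
    A[cbind(1:T, i0 + 2)] <- f
    A
  }
  Ar <- interp_matrix(src[1], target[1])
  Ac <- interp_matrix(src[2], target[2])
  Ar %*% slice %*% t(Ac)
}

#' Embed a predicted slice back into the source grid
#'
#' Resamples the prediction to the crop-box size and places it in a
#' source-shaped canvas whose outside-box value is the air constant, so the
#' restored pseudo-CT has air (not zeros) outside the crop.
#' @param pred_slice 2D prediction (any resolution)
#' @param crop_box 0-based half-open box from \code{\link{crop_bounding_box}}
#' @param source_shape integer pair (rows, cols) of the source grid
#' @param fill canvas value outside the box (default -1000 HU)
#' @export
restore_to_source <- function(pred_slice, crop_box, source_shape,
                              fill = -1000) {
  box_shape <- c(crop_box[3] - crop_box[1], crop_box[4] - crop_box[2])
  resampled <- resample_bilinear(pred_slice, box_shape)
  canvas <- matrix(fill, source_shape[1], source_shape[2])
  canvas[(crop_box[1] + 1):crop_box[3], (crop_box[2] + 1):crop_box[4]] <-
    resampled
  canvas
}

#' Build network-ready slice pairs from a NAC PET / CT volume pair
#'
#' Applies normalize, crop (one box per volume, computed from the PET object
#' and applied identically to the CT), per-slice bilinear resampling to the
#' target matrix, and Softsign — consistently to input and target. Emits one
#' pair per axial slice.
#'
#' @param nac a \code{pet_image} (NAC reconstruction)
#' @param ct the co-registered \code{ct_volume}
#' @param cfg a \code{\link{preprocess_config}}
#' @param source_id identifier stored on each pair
#' @return list of \code{slice_pair} objects (fields: \code{input},
#'   \code{target}, \code{crop_box}, \code{source_id}, \code{slice_index},
#'   \code{source_shape})
#' @export
build_slice_pairs <- function(nac, ct, cfg = preprocess_config(),
                              source_id = "subject") {
  pv <- if (inherits(nac, "pet_image")) nac$voxels else nac
  cv <- if (inherits(ct, "ct_volume")) ct$voxels else ct
  if (!all(dim(pv) == dim(cv)))
    stop("NAC PET and CT must share one grid: ",
         paste(dim(pv), collapse = "x"), " vs ",
         paste(dim(cv), collapse = "x"))
  pet_n <- normalize_pet(pv, cfg)
  ct_n <- normalize_ct(cv, cfg)
  cb <- crop_bounding_box(pet_n, cfg)
  box <- cb$crop_box
  ct_crop <- ct_n[(box[1] + 1):box[3], (box[2] + 1):box[4], , drop = FALSE]
  lapply(seq_len(dim(pv)[3]), function(s) {
    structure(list(
      input = softsign(resample_bilinear(cb$cropped[, , s], cfg$target_matrix)),
      target = softsign(resample_bilinear(ct_crop[, , s], cfg$target_matrix)),
      crop_box = box, source_id = source_id, slice_index = s,
      source_shape = dim(pv)[1:2]), class = "slice_pair")
  })
}

#' Reassemble a 3D pseudo-CT from per-slice network predictions
#'
#' The inverse preprocessing chain: Softsign inversion, rescaling to HU, and
#' restoration into the source grid (air outside the crop box). Network
#' output is clamped to the open Softsign range before inversion.
#'
#' @param preds list of 2D predictions in the Softsign domain
#' @param crop_box shared crop box of the source volume
#' @param source_shape (rows, cols) of the source grid
#' @param spacing voxel spacing of the output volume, mm
#' @param cfg a \code{\link{preprocess_config}}
#' @return a pseudo-CT as a \code{ct_volume}
#' @export
pseudo_ct_from_predictions <- function(preds, crop_box, source_shape, spacing,
                                       cfg = preprocess_config()) {
  lim <- 1 - 1e-9
  slices <- lapply(preds, function(p) {
    hu <- rescale_to_hu(inverse_softsign(pmin(pmax(p, -lim), lim)), cfg)
    restore_to_source(hu, crop_box, source_shape, fill = -1000)
  })
  vox <- array(unlist(slices), c(source_shape, length(slices)))
  new_ct_volume(vox, spacing)
}

#' Serialize / load a slice-pair dataset
#'
#' Input and target stacks are written as NIfTI volumes with a JSON sidecar
#' carrying crop boxes, source ids, slice indices and the preprocessing
#' configuration.
#' @param pairs list of slice pairs from \code{\link{build_slice_pairs}}
#' @param path output prefix (writes \code{<path>_input.nii.gz},
#'   \code{<path>_target.nii.gz}, \code{<path>.json})
#' @export
write_slice_dataset <- function(pairs, path) {
  n <- length(pairs)
  d <- dim(pairs[[1]]$input)
  inp <- array(0, c(d, n)); tgt <- array(0, c(d, n))
  for (i in seq_len(n)) {
    inp[, , i] <- pairs[[i]]$input
    tgt[, , i] <- pairs[[i]]$target
  }
  write_volume(inp, c(1, 1, 1), paste0(path, "_input.nii.gz"))
  write_volume(tgt, c(1, 1, 1), paste0(path, "_target.nii.gz"))
  meta <- list(
    crop_box = lapply(pairs, function(p) p$crop_box),
    source_id = vapply(pairs, function(p) p$source_id, character(1)),
    slice_index = vapply(pairs, function(p) p$slice_index, numeric(1)),
    source_shape = lapply(pairs, function(p) p$source_shape))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_slice_dataset
#' @export
read_slice_dataset <- function(path) {
  inp <- read_volume(paste0(path, "_input.nii.gz"))$voxels
  tgt <- read_volume(paste0(path, "_target.nii.gz"))$voxels
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lapply(seq_len(dim(inp)[3]), function(i) {
    structure(list(input = inp[, , i], target = tgt[, , i],
                   crop_box = unlist(meta$crop_box[i, ]),
                   source_id = meta$source_id[i],
                   slice_index = meta$slice_index[i],
                   source_shape = unlist(meta$source_shape[i, ])),
              class = "slice_pair")
  })
}
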