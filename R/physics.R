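#' Parallel-beam scan geometry
#'
#' A 2D parallel-beam geometry applied slice by slice: \code{n_angles} views
#' uniformly spanning [0, 180) degrees and \code{n_bins} radial bins of width
#' \code{bin_width} mm. \code{n_bins} and \code{bin_width} may be left
#' \code{NULL} and are then resolved against the image grid at projection
#' time (bin width = pixel size, bins covering the grid diagonal).
#'
#' @param n_angles number of view angles (>= 1)
#' @param n_bins number of radial bins, or NULL for automatic
#' @param bin_width radial bin width in mm, or NULL for pixel size
#' @return object of class \code{scan_geometry}
#' @export
scan_geometry <- function(n_angles = 120L, n_bins = NULL, bin_width = NULL) {
  stopifnot(n_angles >= 1)
  structure(list(n_angles = as.integer(n_angles),
                 n_bins = if (is.null(n_bins)) NULL else as.integer(n_bins),
                 bin_width = bin_width),
            class = "scan_geometry")
}

resolve_geometry <- function(geometry, grid_dim, pixel_size) {
  if (is.null(geometry$bin_width)) geometry$bin_width <- pixel_size
  if (is.null(geometry$n_bins)) {
    diag_px <- ceiling(sqrt(sum(grid_dim[1:2]^2)) * pixel_size /
                         geometry$bin_width)
    geometry$n_bins <- as.integer(diag_px + 5L)
  }
  geometry
}

#' Convert CT Hounsfield units to 511 keV linear attenuation coefficients
#'
#' Piecewise-linear scaling: for HU <= 0 (air-to-water segment)
#' \eqn{\mu = \mu_w (1 + HU/1000)} clamped at 0; for HU > 0 (water-to-bone
#' segment) \eqn{\mu = \mu_w + s \cdot HU} with bone slope \code{s}. The map
#' is monotone non-decreasing in HU, zero at -1000 HU, and equals
#' \code{mu_water} at 0 HU.
#'
#' @param ct a \code{ct_volume} or numeric array of HU
#' @param mu_water attenuation of water at 511 keV, 1/cm
#' @param bone_slope attenuation increment per HU above water, 1/cm per HU
#' @return a \code{mu_map} (voxels in 1/cm plus spacing)
#' @export
ct_to_mu <- function(ct, mu_water = 0.096, bone_slope = 2.2e-5) {
  vox <- if (inherits(ct, "ct_volume")) ct$voxels else ct
  spacing <- if (inherits(ct, "ct_volume")) ct$spacing else
    attr(ct, "spacing") %||% c(1, 1, 1)
  if (!all(is.finite(vox))) {
    bad <- which(!apply(is.finite(vox), length(dim(vox)), all))
    stop("non-finite HU values in slice(s): ", paste(bad, collapse = ", "))
  }
  mu <- ifelse(vox <= 0,
               pmax(mu_water * (1 + vox / 1000), 0),
               mu_water + bone_slope * vox)
  structure(list(voxels = mu, spacing = spacing), class = "mu_map")
}

#' Attenuated parallel-beam forward projection
#'
#' Expected counts for ray r are
#' \eqn{count\_scale \cdot e^{-\int_r \mu\, dl} \cdot \int_r a\, dl}, the
#' standard PET coincidence model in which the attenuation factor depends on
#' the full line of response and not on the emission point. Line integrals
#' use a pixel-driven projector with linear bin interpolation; path lengths
#' are in cm (mu in 1/cm). With \code{seed} given, each ray receives an
#' independent Poisson draw.
#'
#' @param activity an \code{activity_map} (or \code{pet_image}) in Bq/ml
#' @param mu a \code{mu_map} on the same grid, or NULL for no attenuation
#' @param geometry a \code{\link{scan_geometry}}
#' @param count_scale detector sensitivity scaling (counts per Bq/ml cm);
#'   the default gives roughly 2e5 counts per slice for the default phantom
#' @param seed integer seed for Poisson noise, or NULL for noiseless
#' @return a \code{sinogram}: counts array (n_angles, n_bins, n_slices) plus
#'   geometry, grid metadata and the count scale (the reconstruction reuses
#'   both as its system model)
#' @export
forward_project <- function(activity, mu = NULL, geometry = scan_geometry(),
                            count_scale = 2e-3, seed = NULL) {
  vox <- activity$voxels
  spacing <- activity$spacing
  dims <- dim(vox)
  if (!is.null(mu) && !all(dim(mu$voxels) == dims))
    stop("activity and mu must share one grid: ",
         paste(dims, collapse = "x"), " vs ",
         paste(dim(mu$voxels), collapse = "x"))
  geometry <- resolve_geometry(geometry, dims, spacing[1])
  angles <- seq(0, pi, length.out = geometry$n_angles + 1)[1:geometry$n_angles]
  bw_px <- geometry$bin_width / spacing[1]
  px_cm <- spacing[1] / 10

  # coverage check against the activity support
  supp <- which(apply(vox > 0, c(1, 2), any), arr.ind = TRUE)
  if (nrow(supp) > 0) {
    cc <- (dims[1:2] + 1) / 2
    rmax <- max(sqrt((supp[, 1] - cc[1])^2 + (supp[, 2] - cc[2])^2))
    if ((geometry$n_bins - 1) / 2 * bw_px < rmax + 1)
      stop("scan geometry does not cover the activity support (",
           geometry$n_bins, " bins of ", geometry$bin_width, " mm)")
  }

  n_slices <- dims[3]
  counts <- array(0, c(geometry$n_angles, geometry$n_bins, n_slices))
  for (s in seq_len(n_slices)) {
    proj_act <- cpp_radon_forward(vox[, , s], angles, geometry$n_bins,
                                  bw_px, px_cm)
    att <- if (!is.null(mu))
      exp(-cpp_radon_forward(mu$voxels[, , s], angles, geometry$n_bins,
                             bw_px, px_cm))
    else 1
    expected <- count_scale * att * proj_act
    counts[, , s] <- if (!is.null(seed))
      with_seed(substream_seed(seed, "noise", s),
                array(stats::rpois(length(expected), expected), dim(expected)))
    else expected
  }
  structure(list(counts = counts, geometry = geometry,
                 noise_realized = !is.null(seed), seed = seed,
                 count_scale = count_scale, img_dim = dims,
                 spacing = spacing),
            class = "sinogram")
}

#' Reconstruction configuration
#'
#' @param n_iterations full OSEM iterations (each visits every subset once)
#' @param n_subsets number of angle-interleaved subsets; must divide the
#'   number of view angles
#' @param post_filter_fwhm isotropic Gaussian post filter FWHM in mm (0 = off)
#' @param epsilon ratio-guard constant in MLEM divisions
#' @param use_attenuation fold attenuation factors into the system model
#' @export
recon_config <- function(n_iterations = 24L, n_subsets = 3L,
                         post_filter_fwhm = 4, epsilon = 1e-12,
                         use_attenuation = TRUE) {
  stopifnot(n_iterations >= 1, n_subsets >= 1, epsilon > 0,
            post_filter_fwhm >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 post_filter_fwhm = post_filter_fwhm, epsilon = epsilon,
                 use_attenuation = use_attenuation),
            class = "recon_config")
}

#' Ordered-subsets MLEM reconstruction
#'
#' Multiplicative EM updates with the attenuation factors folded into the
#' system model (when enabled and a mu map is supplied), uniform positive
#' initialization, interleaved angle subsets (angle i in subset i mod S), and
#' an optional Gaussian post filter applied once at the end. Rays and pixels
#' with zero forward sensitivity are excluded from updates rather than
#' divided by. Non-negativity is guaranteed by construction.
#'
#' @param sino a \code{sinogram} from \code{\link{forward_project}}
#' @param mu a \code{mu_map} on the image grid, or NULL
#' @param config a \code{\link{recon_config}}
#' @param provenance provenance tag stored on the image
#' @param track_loglik if TRUE, record the Poisson log-likelihood of the
#'   fitted sinogram after every full iteration (slice 1 only)
#' @return a \code{pet_image} (Bq/ml); with \code{track_loglik}, attribute
#'   \code{loglik} carries the per-iteration log-likelihood trace
#' @export
reconstruct_osem <- function(sino, mu = NULL, config = recon_config(),
                             provenance = c("NAC", "CTAC", "deepAC", "truth"),
                             track_loglik = FALSE) {
  provenance <- match.arg(provenance)
  geom <- sino$geometry
  if (geom$n_angles %% config$n_subsets != 0)
    stop("n_subsets (", config$n_subsets, ") must divide n_angles (",
         geom$n_angles, ")")
  if (any(sino$counts < 0)) stop("sinogram counts must be >= 0")
  dims <- sino$img_dim
  angles <- seq(0, pi, length.out = geom$n_angles + 1)[1:geom$n_angles]
  bw_px <- geom$bin_width / sino$spacing[1]
  px_cm <- sino$spacing[1] / 10
  eps <- config$epsilon
  subsets <- lapply(seq_len(config$n_subsets) - 1L,
                    function(s) which(seq_len(geom$n_angles) %% config$n_subsets
                                      == s %% config$n_subsets))
  out <- array(0, dims)
  loglik <- if (track_loglik) numeric(config$n_iterations) else NULL

  for (sl in seq_len(dims[3])) {
    y <- sino$counts[, , sl]
    att_full <- if (config$use_attenuation && !is.null(mu))
      exp(-cpp_radon_forward(mu$voxels[, , sl], angles, geom$n_bins,
                             bw_px, px_cm))
    else matrix(1, geom$n_angles, geom$n_bins)
    # per-subset sensitivity images: A^T 1
    sens <- lapply(subsets, function(ix)
      cpp_radon_backward(sino$count_scale * att_full[ix, , drop = FALSE],
                         angles[ix], dims[1], dims[2], bw_px, px_cm))
    x <- array(1, dims[1:2])
    for (it in seq_len(config$n_iterations)) {
      for (k in seq_along(subsets)) {
        ix <- subsets[[k]]
        fp <- sino$count_scale * att_full[ix, , drop = FALSE] *
          cpp_radon_forward(x, angles[ix], geom$n_bins, bw_px, px_cm)
        ratio <- y[ix, , drop = FALSE] / (fp + eps)
        bp <- cpp_radon_backward(sino$count_scale *
                                   att_full[ix, , drop = FALSE] * ratio,
                                 angles[ix], dims[1], dims[2], bw_px, px_cm)
        s_k <- sens[[k]]
        upd <- which(s_k > 0)
        x[upd] <- x[upd] * bp[upd] / s_k[upd]
        x[s_k <= 0] <- 0
      }
      if (track_loglik && sl == 1) {
        fp_all <- sino$count_scale * att_full *
          cpp_radon_forward(x, angles, geom$n_bins, bw_px, px_cm)
        loglik[it] <- sum(y * log(fp_all + eps) - fp_all)
      }
    }
    out[, , sl] <- x
  }
  img <- structure(list(voxels = out, spacing = sino$spacing,
                        provenance = provenance),
                   class = "pet_image")
  if (config$post_filter_fwhm > 0)
    img <- apply_post_filter(img, config$post_filter_fwhm)
  if (track_loglik) attr(img, "loglik") <- loglik
  img
}

gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

blur_slice <- function(m, k) {
  r <- (length(k) - 1) / 2
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W)
  for (d in -r:r) {             # rows
    i_src <- pmin(pmax(seq_len(H) + d, 1L), H)
    valid <- seq_len(H) + d >= 1 & seq_len(H) + d <= H
    tmp[valid, ] <- tmp[valid, ] + k[d + r + 1] * m[(seq_len(H) + d)[valid], ]
  }
  out <- matrix(0, H, W)
  for (d in -r:r) {             # columns
    valid <- seq_len(W) + d >= 1 & seq_len(W) + d <= W
    out[, valid] <- out[, valid] + k[d + r + 1] * tmp[, (seq_len(W) + d)[valid]]
  }
  out
}

#' Apply an isotropic Gaussian post filter
#'
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})} in mm, converted to pixels via the
#' image spacing; applied in-plane per axial slice with a normalized,
#' zero-padded kernel. \code{fwhm = 0} is the identity.
#'
#' @param img a \code{pet_image} (or any object with voxels + spacing)
#' @param fwhm filter full width at half maximum, mm
#' @return filtered image of the same class
#' @export
apply_post_filter <- function(img, fwhm) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(img)
  sigma_px <- fwhm / (2 * sqrt(2 * log(2))) / img$spacing[1]
  k <- gaussian_kernel_1d(sigma_px)
  vox <- img$voxels
  for (s in seq_len(dim(vox)[3])) vox[, , s] <- blur_slice(vox[, , s], k)
  img$voxels <- vox
  img
}

#' Poisson log-likelihood of a fitted sinogram
#'
#' \eqn{\sum_r y_r \log(\bar y_r + \epsilon) - \bar y_r} (data-only terms).
#' Used by the MLEM monotonicity diagnostics.
#' @param y observed counts
#' @param ybar fitted expected counts
#' @param eps guard constant
#' @export
sinogram_loglik <- function(y, ybar, eps = 1e-12) {
  sum(y * log(ybar + eps) - ybar)
}

#' Calibrate the projection count scale
#'
#' Returns the \code{count_scale} for which the mean expected counts per
#' slice of the given phantom equal \code{target_counts}.
#' @param activity,mu,geometry as in \code{\link{forward_project}}
#' @param target_counts desired mean total counts per slice
#' @export
calibrate_count_scale <- function(activity, mu, geometry = scan_geometry(),
                                  target_counts = 2e5) {
  sino <- forward_project(activity, mu, geometry, count_scale = 1)
  target_counts / mean(apply(sino$counts, 3, sum))
}
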