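#' Specification of a synthetic head phantom cohort
#'
#' Describes the randomized geometry and intensity model of a digital head
#' phantom: an elliptical soft-tissue head with a closed bone skull shell, a
#' scalp layer outside the skull, optional internal air cavities
#' (sinus-like), brain-like FDG uptake with cortical/deep-gray/white-matter
#' contrast, and optional abnormalities (a skull defect or a focal hot
#' lesion). All stochastic choices are driven by \code{seed}; phantom
#' \code{index} uses an independent substream so cohorts are reproducible
#' under reordering.
#'
#' Default Hounsfield values (air -1000, soft tissue 40, bone 1200, each with
#' +/-5\% per-phantom jitter and mild voxel noise) sit well inside the
#' standard discretization bands (air < -400 HU, bone > 300 HU), so the
#' generator's internal tissue labels are recoverable exactly by
#' thresholding.
#'
#' @param grid_size pixels per side of each (square) axial slice
#' @param n_slices number of axial slices
#' @param pixel_size in-plane pixel size, mm
#' @param slice_spacing axial spacing, mm
#' @param head_axes_range range (mm) of the outer-head ellipse semi-axes
#' @param skull_thickness_range range (mm) of the bone shell thickness
#' @param scalp_thickness soft-tissue layer outside the skull, mm
#' @param n_air_cavities_range integer range of internal air cavities
#' @param hu_values named HU per tissue: \code{air}, \code{soft}, \code{bone}
#' @param hu_jitter per-phantom multiplicative HU jitter fraction
#' @param hu_noise_sd voxelwise Gaussian HU noise, HU
#' @param activity_levels named Bq/ml per region: \code{background} (scalp
#'   and non-brain soft tissue), \code{gray}, \code{white}, \code{lesion}
#' @param abnormality one of \code{"none"}, \code{"skull_defect"},
#'   \code{"hot_lesion"}
#' @param seed integer master seed
#' @return an object of class \code{phantom_spec}
#' @export
phantom_spec <- function(grid_size = 64L, n_slices = 8L, pixel_size = 3.5,
                         slice_spacing = 3.5,
                         head_axes_range = c(60, 85),
                         skull_thickness_range = c(6, 10),
                         scalp_thickness = 6,
                         n_air_cavities_range = c(1L, 3L),
                         hu_values = c(air = -1000, soft = 40, bone = 1200),
                         hu_jitter = 0.05, hu_noise_sd = 20,
                         activity_levels = c(background = 1500, gray = 12000,
                                             white = 4000, lesion = 24000),
                         abnormality = c("none", "skull_defect", "hot_lesion"),
                         seed = 1L) {
  abnormality <- match.arg(abnormality)
  spec <- list(grid_size = as.integer(grid_size),
               n_slices = as.integer(n_slices),
               pixel_size = pixel_size, slice_spacing = slice_spacing,
               head_axes_range = head_axes_range,
               skull_thickness_range = skull_thickness_range,
               scalp_thickness = scalp_thickness,
               n_air_cavities_range = as.integer(n_air_cavities_range),
               hu_values = hu_values, hu_jitter = hu_jitter,
               hu_noise_sd = hu_noise_sd,
               activity_levels = activity_levels,
               abnormality = abnormality, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  hv <- spec$hu_values
  if (!(hv[["air"]] < -400)) stop("hu_values['air'] must be < -400 HU")
  if (!(hv[["soft"]] > -400 && hv[["soft"]] < 300))
    stop("hu_values['soft'] must lie in (-400, 300) HU")
  if (!(hv[["bone"]] > 300)) stop("hu_values['bone'] must be > 300 HU")
  if (any(spec$activity_levels < 0)) stop("activity_levels must be >= 0")
  if (spec$grid_size < 8) stop("grid_size must be >= 8")
  if (diff(range(spec$head_axes_range)) < 0) stop("invalid head_axes_range")
  invisible(spec)
}

#' Construct a CT volume
#'
#' Voxels in Hounsfield units, clamped to [-1024, 3000]; \code{tissue}
#' optionally carries a generator-internal tissue label array.
#' @param voxels 3D HU array
#' @param spacing mm triple
#' @param origin mm triple
#' @param tissue optional integer label array (0 air, 1 soft, 2 bone)
#' @export
new_ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                          tissue = NULL) {
  voxels <- pmin(pmax(voxels, -1024), 3000)
  stopifnot(all(spacing > 0))
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 tissue = tissue),
            class = "ct_volume")
}

#' Construct a tracer activity map
#'
#' Voxels in Bq/ml (non-negative); \code{label_map} optionally carries
#' integer ROI ids (0 = background).
#' @param voxels 3D Bq/ml array
#' @param spacing mm triple
#' @param origin mm triple
#' @param label_map optional integer ROI array
#' @export
new_activity_map <- function(voxels, spacing, origin = c(0, 0, 0),
                             label_map = NULL) {
  stopifnot(all(voxels >= 0), all(spacing > 0))
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 label_map = label_map),
            class = "activity_map")
}

#' Generate one paired CT / activity phantom
#'
#' Draws the phantom's geometry from the spec's ranges using the substream
#' seed for \code{index} and rasterizes it slice by slice. Slice axes taper
#' towards the first and last slice (head-like shape). The returned CT
#' carries the generator's internal tissue label array (0 air, 1 soft,
#' 2 bone); the activity map carries a region-of-interest label map
#' (0 background, then cortical quadrants, deep gray, white matter, and a
#' lesion label when present) used for ROI statistics downstream.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param index phantom number (>= 0); selects the per-phantom substream
#' @return list with elements \code{ct} (class \code{ct_volume}) and
#'   \code{activity} (class \code{activity_map})
#' @export
generate_phantom <- function(spec, index = 0L) {
  validate_phantom_spec(spec)
  stopifnot(index >= 0)
  seed <- substream_seed(spec$seed, "phantom", index)
  with_seed(seed, {
    g <- spec$grid_size; ns <- spec$n_slices; px <- spec$pixel_size
    a <- stats::runif(1, spec$head_axes_range[1], spec$head_axes_range[2])
    b <- stats::runif(1, spec$head_axes_range[1], spec$head_axes_range[2])
    skull_t <- stats::runif(1, spec$skull_thickness_range[1],
                            spec$skull_thickness_range[2])
    if (skull_t + spec$scalp_thickness >= min(a, b))
      stop("invalid geometry: skull thickness >= smaller head semi-axis")
    n_cav <- if (spec$n_air_cavities_range[2] > spec$n_air_cavities_range[1])
      sample(spec$n_air_cavities_range[1]:spec$n_air_cavities_range[2], 1)
    else spec$n_air_cavities_range[1]
    cav <- if (n_cav > 0) data.frame(
      u = stats::runif(n_cav, 0.10, 0.45),
      ang = stats::runif(n_cav, 0, 2 * pi),
      r = stats::runif(n_cav, 8, 15),
      z = stats::runif(n_cav, -0.5, 0.5)) else NULL
    jit <- 1 + stats::runif(3, -spec$hu_jitter, spec$hu_jitter)
    hv <- spec$hu_values * jit
    defect_ang <- stats::runif(1, 0, 2 * pi)
    lesion <- list(u = stats::runif(1, 0.15, 0.55),
                   ang = stats::runif(1, 0, 2 * pi),
                   r = stats::runif(1, 5, 8),
                   z = stats::runif(1, -0.4, 0.4))
    noise <- if (spec$hu_noise_sd > 0)
      array(stats::rnorm(g * g * ns, 0, spec$hu_noise_sd), c(g, g, ns))
    else array(0, c(g, g, ns))

    ct <- array(hv[["air"]], c(g, g, ns))
    tissue <- array(0L, c(g, g, ns))          # 0 air, 1 soft, 2 bone
    act <- array(0, c(g, g, ns))
    labels <- array(0L, c(g, g, ns))
    al <- spec$activity_levels

    cc <- (g + 1) / 2
    xs <- ((1:g) - cc) * px                   # mm, column axis
    ys <- ((1:g) - cc) * px                   # mm, row axis
    X <- matrix(xs, g, g, byrow = TRUE)       # x varies along columns
    Y <- matrix(ys, g, g)                     # y varies along rows
    zc <- (ns + 1) / 2
    TH <- atan2(Y, X)

    for (s in seq_len(ns)) {
      zn <- if (ns > 1) (s - zc) / (ns / 2) else 0
      sc <- sqrt(pmax(1 - 0.25 * zn^2, 0.05))
      as_ <- a * sc; bs_ <- b * sc
      R <- sqrt((X / as_)^2 + (Y / bs_)^2)    # normalized elliptical radius
      mn <- min(as_, bs_)
      r1 <- 1 - spec$scalp_thickness / mn     # skull outer surface
      r2 <- r1 - skull_t / mn                 # skull inner surface
      if (r2 <= 0.15) stop("invalid geometry: skull leaves no room for brain")
      head <- R <= 1
      shell <- head & R > r2 & R <= r1
      brain <- R <= r2
      t_s <- ifelse(head, 1L, 0L)
      t_s[shell] <- 2L
      if (spec$abnormality == "skull_defect") {
        sector <- ((TH - defect_ang) %% (2 * pi)) < (pi / 3)
        t_s[shell & sector] <- 1L             # missing bone, filled by soft
      }
      # internal air cavities: spheres in mm coordinates
      if (!is.null(cav)) {
        zmm <- (s - zc) * spec$slice_spacing
        for (k in seq_len(nrow(cav))) {
          cxk <- a * cav$u[k] * cos(cav$ang[k])
          cyk <- b * cav$u[k] * sin(cav$ang[k])
          czk <- cav$z[k] * (ns / 2) * spec$slice_spacing
          d2 <- (X - cxk)^2 + (Y - cyk)^2 + (zmm - czk)^2
          inside <- d2 <= cav$r[k]^2 & brain
          t_s[inside] <- 0L
        }
      }
      ct_s <- hv[["air"]] + (t_s == 1L) * (hv[["soft"]] - hv[["air"]]) +
        (t_s == 2L) * (hv[["bone"]] - hv[["air"]])
      ct[, , s] <- ct_s + noise[, , s]

      # activity + ROI labels on the brain interior (soft voxels only)
      soft_brain <- brain & t_s == 1L
      ribbon <- soft_brain & R > 0.68 * r2
      core <- soft_brain & R <= 0.30 * r2
      white <- soft_brain & !ribbon & !core
      lab_s <- array(0L, dim(t_s))
      ang_ok <- function(lo, hi) TH >= lo & TH < hi
      lab_s[ribbon & ang_ok(-pi / 4, pi / 4)] <- 1L       # right cortex
      lab_s[ribbon & ang_ok(pi / 4, 3 * pi / 4)] <- 2L    # posterior cortex
      lab_s[ribbon & (TH >= 3 * pi / 4 | TH < -3 * pi / 4)] <- 3L  # left
      lab_s[ribbon & ang_ok(-3 * pi / 4, -pi / 4)] <- 4L  # anterior cortex
      lab_s[core] <- 5L                                   # deep gray
      lab_s[white] <- 6L                                  # white matter
      act_s <- array(0, dim(t_s))
      act_s[t_s == 1L & !soft_brain] <- al[["background"]]
      act_s[lab_s %in% c(1L, 2L, 3L, 4L, 5L)] <- al[["gray"]]
      act_s[lab_s == 6L] <- al[["white"]]
      if (spec$abnormality == "hot_lesion") {
        zmm <- (s - zc) * spec$slice_spacing
        cxk <- a * lesion$u * cos(lesion$ang)
        cyk <- b * lesion$u * sin(lesion$ang)
        czk <- lesion$z * (ns / 2) * spec$slice_spacing
        inside <- ((X - cxk)^2 + (Y - cyk)^2 + (zmm - czk)^2) <= lesion$r^2 &
          soft_brain
        act_s[inside] <- al[["lesion"]]
        lab_s[inside] <- 7L
      }
      act[, , s] <- act_s
      labels[, , s] <- lab_s
      tissue[, , s] <- t_s
    }
    spacing <- c(px, px, spec$slice_spacing)
    list(ct = new_ct_volume(ct, spacing, tissue = tissue),
         activity = new_activity_map(act, spacing, label_map = labels))
  })
}

#' Generate and write a train/test phantom cohort
#'
#' Writes per-phantom NIfTI volumes (CT, activity, ROI labels) plus a
#' tab-delimited manifest with disjoint train/test splits. The split is a
#' function of the spec seed only.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param n_train,n_test cohort sizes (>= 1)
#' @param out_dir output directory
#' @param overwrite allow overwriting an existing manifest
#' @return the manifest as a data.frame (invisibly written to
#'   \code{manifest.tsv})
#' @export
make_dataset <- function(spec, n_train, n_test, out_dir, overwrite = FALSE) {
  stopifnot(n_train >= 1, n_test >= 1)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite)
    stop("refusing to overwrite existing dataset at ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  split <- rep("train", n)
  test_ids <- with_seed(substream_seed(spec$seed, "split"),
                        sample(seq_len(n), n_test))
  split[test_ids] <- "test"
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec, index = i - 1L)
    id <- sprintf("phantom_%03d", i - 1L)
    ct_path <- file.path(out_dir, paste0(id, "_ct.nii.gz"))
    act_path <- file.path(out_dir, paste0(id, "_act.nii.gz"))
    lab_path <- file.path(out_dir, paste0(id, "_labels.nii.gz"))
    write_volume(ph$ct$voxels, ph$ct$spacing, ct_path)
    write_volume(ph$activity$voxels, ph$activity$spacing, act_path)
    write_volume(ph$activity$label_map, ph$activity$spacing, lab_path)
    rows[[i]] <- data.frame(id = id, split = split[i], ct_path = ct_path,
                            act_path = act_path, label_path = lab_path,
                            seed = substream_seed(spec$seed, "phantom", i - 1L))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}
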