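#' Discretize a CT (or pseudo-CT) into air / soft tissue / bone
#'
#' Threshold rule with strict inequalities: bone if HU > 300, air if
#' HU < -400, otherwise soft tissue; values exactly at a threshold are soft.
#' @param ct a \code{ct_volume} or numeric HU array
#' @param air_below,bone_above thresholds in HU
#' @return integer array of class \code{tissue_labels}: 0 air, 1 soft, 2 bone
#' @export
discretize_ct <- function(ct, air_below = -400, bone_above = 300) {
  v <- if (inherits(ct, "ct_volume")) ct$voxels else ct
  stopifnot(all(is.finite(v)))
  lab <- array(1L, dim(v))
  lab[v < air_below] <- 0L
  lab[v > bone_above] <- 2L
  structure(lab, class = c("tissue_labels", class(lab)))
}

tissue_code <- function(tissue) {
  if (is.numeric(tissue)) return(as.integer(tissue))
  switch(match.arg(tissue, c("air", "soft", "bone")),
         air = 0L, soft = 1L, bone = 2L)
}

#' Dice overlap coefficient for one tissue class
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} over the voxel sets of the given tissue.
#' When both sets are empty the overlap is vacuously perfect and 1 is
#' returned (with a message). An optional mask restricts the comparison
#' (e.g. to in-head air cavities).
#' @param a,b tissue label arrays of one shape
#' @param tissue "air", "soft", "bone" or an integer code
#' @param mask optional logical array
#' @export
dice <- function(a, b, tissue = "soft", mask = NULL) {
  if (!all(dim(a) == dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  code <- tissue_code(tissue)
  A <- a == code; B <- b == code
  if (!is.null(mask)) { A <- A & mask; B <- B & mask }
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) {
    message("dice: both label sets empty for tissue ", tissue,
            "; returning 1")
    return(1)
  }
  2 * sum(A & B) / (na + nb)
}

#' Mean absolute error between pseudo-CT and reference CT
#'
#' @param pseudo,truth \code{ct_volume}s or HU arrays on one grid
#' @param mask optional logical array restricting the mean
#' @return MAE in HU
#' @export
mae <- function(pseudo, truth, mask = NULL) {
  pv <- if (inherits(pseudo, "ct_volume")) pseudo$voxels else pseudo
  tv <- if (inherits(truth, "ct_volume")) truth$voxels else truth
  stopifnot(all(dim(pv) == dim(tv)))
  d <- abs(pv - tv)
  if (!is.null(mask)) {
    if (sum(mask) == 0) stop("mae: empty mask")
    d <- d[mask]
  }
  mean(d)
}

#' Pixel-wise relative PET error map
#'
#' Signed percentage error of a test reconstruction against a reference:
#' \eqn{Err = (I_{test} - I_{ref}) / I_{ref} \times 100\%}, with the
#' absolute map alongside. Voxels whose reference intensity falls below
#' \code{floor_frac} of the reference maximum are excluded from the mask
#' (relative error is undefined near zero).
#'
#' @param pet_test,pet_ref \code{pet_image}s or arrays on one grid
#' @param mask optional logical array intersected with the intensity floor
#' @param floor_frac reference-intensity floor as a fraction of the max
#' @return list with \code{err}, \code{abs_err} (NA outside the mask) and
#'   the final \code{mask}
#' @export
error_map <- function(pet_test, pet_ref, mask = NULL, floor_frac = 0.01) {
  tv <- if (inherits(pet_test, "pet_image")) pet_test$voxels else pet_test
  rv <- if (inherits(pet_ref, "pet_image")) pet_ref$voxels else pet_ref
  stopifnot(all(dim(tv) == dim(rv)))
  m <- rv > floor_frac * max(rv)
  if (!is.null(mask)) m <- m & mask
  if (sum(m) == 0) stop("error_map: empty mask after intensity flooring")
  err <- array(NA_real_, dim(tv))
  err[m] <- (tv[m] - rv[m]) / rv[m] * 100
  list(err = err, abs_err = abs(err), mask = m)
}

paired_t_p <- function(x, y) {
  d <- x - y
  if (length(d) < 2) stop("paired t-test needs >= 2 subjects")
  if (stats::sd(d) == 0) {
    message("paired t-test: all differences identical; p reported as 1")
    return(1)
  }
  stats::t.test(x, y, paired = TRUE)$p.value
}

#' ROI-level PET error statistics with paired t-tests
#'
#' For each subject, the relative error map of the test reconstruction
#' against the reference is averaged per ROI (signed and absolute); the
#' across-subject mean, standard deviation, minimum and maximum of those
#' subject-level ROI means are reported alongside a two-sided paired t-test
#' on the subject-level ROI-mean activities (test vs reference), with an
#' uncorrected 0.05 flag and a Bonferroni flag at \code{alpha / m_tests}
#' (0.05 / 21 reproduces the conventional 0.0024 level). Two pooled summary
#' rows are emitted: an ROI-averaged one and a pooled-voxel one.
#'
#' @param pet_test_list,pet_ref_list per-subject \code{pet_image}s (or
#'   arrays)
#' @param roi_labels an integer ROI label array (0 = background) shared by
#'   all subjects, or a per-subject list of them
#' @param alpha significance level before correction
#' @param m_tests Bonferroni divisor; defaults to the number of ROIs
#' @param floor_frac reference-intensity floor for the error maps
#' @return a data.frame (one row per ROI plus the two summary rows)
#' @export
roi_statistics <- function(pet_test_list, pet_ref_list, roi_labels,
                           alpha = 0.05, m_tests = NULL, floor_frac = 0.01) {
  n <- length(pet_test_list)
  if (n < 2) stop("roi_statistics needs >= 2 subjects")
  stopifnot(length(pet_ref_list) == n)
  labs <- if (is.list(roi_labels)) roi_labels else
    replicate(n, roi_labels, simplify = FALSE)
  ids <- sort(setdiff(unique(as.vector(labs[[1]])), 0))
  if (is.null(m_tests)) m_tests <- length(ids)
  thr <- alpha / m_tests

  per <- array(NA_real_, c(n, length(ids), 4),
               dimnames = list(NULL, ids, c("err", "abs", "act_t", "act_r")))
  pooled_err <- c(); pooled_abs <- c()
  for (s in seq_len(n)) {
    tv <- if (inherits(pet_test_list[[s]], "pet_image"))
      pet_test_list[[s]]$voxels else pet_test_list[[s]]
    rv <- if (inherits(pet_ref_list[[s]], "pet_image"))
      pet_ref_list[[s]]$voxels else pet_ref_list[[s]]
    em <- error_map(tv, rv, floor_frac = floor_frac)
    for (k in seq_along(ids)) {
      sel <- labs[[s]] == ids[k] & em$mask
      if (sum(sel) == 0) stop("ROI ", ids[k], " empty in subject ", s)
      per[s, k, "err"] <- mean(em$err[sel])
      per[s, k, "abs"] <- mean(em$abs_err[sel])
      per[s, k, "act_t"] <- mean(tv[sel])
      per[s, k, "act_r"] <- mean(rv[sel])
    }
    brain <- labs[[s]] > 0 & em$mask
    pooled_err <- c(pooled_err, mean(em$err[brain]))
    pooled_abs <- c(pooled_abs, mean(em$abs_err[brain]))
  }
  row_for <- function(name, e, a, p) {
    data.frame(region = name,
               mean_err = mean(e), sd_err = stats::sd(e),
               min_err = min(e), max_err = max(e),
               mean_abs_err = mean(a), sd_abs_err = stats::sd(a),
               min_abs_err = min(a), max_abs_err = max(a),
               p_value = p,
               significant_uncorrected = is.finite(p) && p < alpha,
               significant_bonferroni = is.finite(p) && p < thr)
  }
  out <- do.call(rbind, lapply(seq_along(ids), function(k) {
    row_for(paste0("roi_", ids[k]), per[, k, "err"], per[, k, "abs"],
            paired_t_p(per[, k, "act_t"], per[, k, "act_r"]))
  }))
  roi_avg_err <- rowMeans(matrix(per[, , "err"], n, length(ids)))
  roi_avg_abs <- rowMeans(matrix(per[, , "abs"], n, length(ids)))
  out <- rbind(out,
               row_for("all_regions_roi_mean", roi_avg_err, roi_avg_abs,
                       NA_real_),
               row_for("all_regions_pooled", pooled_err, pooled_abs,
                       NA_real_))
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' In-head mask from a tissue label array
#'
#' The head is everything that is not background air: soft and bone voxels
#' plus enclosed air cavities, found by flood-filling the outside air from
#' the slice border and inverting.
#' @param tissue integer tissue array (0 air, 1 soft, 2 bone)
#' @return logical array
#' @export
head_mask_from_tissue <- function(tissue) {
  d <- dim(tissue)
  out <- array(FALSE, d)
  for (s in seq_len(d[3])) {
    air <- tissue[, , s] == 0L
    outside <- matrix(FALSE, d[1], d[2])
    outside[1, ] <- air[1, ]; outside[d[1], ] <- air[d[1], ]
    outside[, 1] <- outside[, 1] | air[, 1]
    outside[, d[2]] <- outside[, d[2]] | air[, d[2]]
    repeat {
      grown <- outside
      grown[-1, ] <- grown[-1, ] | outside[-d[1], ]
      grown[-d[1], ] <- grown[-d[1], ] | outside[-1, ]
      grown[, -1] <- grown[, -1] | outside[, -d[2]]
      grown[, -d[2]] <- grown[, -d[2]] | outside[, -1]
      grown <- grown & air
      if (all(grown == outside)) break
      outside <- grown
    }
    out[, , s] <- !outside
  }
  out
}
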