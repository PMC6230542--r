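#' Assemble a full pipeline configuration
#'
#' Bundles the phantom spec, scan geometry, reconstruction, preprocessing,
#' network and training configurations under one master seed. Desk mode uses
#' a 64x64, 8-slice phantom grid and a reduced three-stage network;
#' full-scale mode switches to the 200x180 matrix, the 13-layer
#' encoder and the full 50-epoch recipe (batch 12, learning rate 0.001 in
#' both modes). The master seed fans out to named substreams (phantom
#' geometry, train/test split, count noise, weight init, batch shuffling) so
#' stages are independently reproducible.
#'
#' @param master_seed integer master seed
#' @param mode "desk" or "full_scale"
#' @param n_train,n_test cohort sizes
#' @param n_epochs training epochs (default: 64 desk, 50 full-size)
#' @param count_scale projection count scaling (see
#'   \code{\link{forward_project}})
#' @return a \code{run_config} list
#' @export
run_config <- function(master_seed = 1L, mode = c("desk", "full_scale"),
                       n_train = 40L, n_test = 8L, n_epochs = NULL,
                       count_scale = 2e-3) {
  mode <- match.arg(mode)
  desk <- mode == "desk"
  if (is.null(n_epochs)) n_epochs <- if (desk) 64L else 50L
  cfg <- list(
    master_seed = as.integer(master_seed), mode = mode,
    n_train = as.integer(n_train), n_test = as.integer(n_test),
    phantom = phantom_spec(grid_size = if (desk) 64L else 200L,
                           n_slices = 8L,
                           pixel_size = if (desk) 3.5 else 1.2,
                           slice_spacing = 3.5,
                           seed = substream_seed(master_seed, "phantoms")),
    geometry = scan_geometry(n_angles = 120L),
    recon = recon_config(n_iterations = 24L, n_subsets = 3L,
                         post_filter_fwhm = 4),
    preprocess = preprocess_config(target_matrix = if (desk) c(64L, 64L)
                                   else c(200L, 180L)),
    network = if (desk) network_spec(list(c(1, 16), c(1, 32), c(2, 64)))
    else full_network_spec(),
    train = train_config(learning_rate = 0.001, batch_size = 12L,
                         n_epochs = n_epochs,
                         seed = substream_seed(master_seed, "train")),
    count_scale = count_scale)
  class(cfg) <- "run_config"
  cfg
}

simulate_cohort <- function(cfg) {
  n <- cfg$n_train + cfg$n_test
  split <- rep("train", n)
  split[with_seed(substream_seed(cfg$phantom$seed, "split"),
                  sample(seq_len(n), cfg$n_test))] <- "test"
  phantoms <- lapply(seq_len(n) - 1L,
                     function(i) generate_phantom(cfg$phantom, i))
  list(phantoms = phantoms, split = split)
}

scan_phantom <- function(ph, cfg, index) {
  mu_true <- ct_to_mu(ph$ct)
  sino <- forward_project(ph$activity, mu_true, cfg$geometry,
                          count_scale = cfg$count_scale,
                          seed = substream_seed(cfg$master_seed, "counts",
                                                index))
  nac_cfg <- cfg$recon; nac_cfg$use_attenuation <- FALSE
  nac <- reconstruct_osem(sino, NULL, nac_cfg, provenance = "NAC")
  list(mu_true = mu_true, sino = sino, nac = nac)
}

#' Synthesize a pseudo-CT volume from a NAC PET reconstruction
#'
#' Preprocesses the NAC volume (crop box computed from the PET object),
#' runs slice-wise network inference, and applies the inverse chain back to
#' a Hounsfield-unit volume on the source grid.
#' @param net trained \code{ced_network}
#' @param nac a NAC \code{pet_image}
#' @param cfg a \code{\link{preprocess_config}}
#' @return a pseudo-CT \code{ct_volume}
#' @export
synthesize_pseudo_ct <- function(net, nac, cfg = preprocess_config()) {
  pet_n <- normalize_pet(nac$voxels, cfg)
  cb <- crop_bounding_box(pet_n, cfg)
  preds <- lapply(seq_len(dim(nac$voxels)[3]), function(s) {
    x <- softsign(resample_bilinear(cb$cropped[, , s], cfg$target_matrix))
    predict_slices(net, x)
  })
  pseudo_ct_from_predictions(preds, cb$crop_box, dim(nac$voxels)[1:2],
                             nac$spacing, cfg)
}

#' Run the complete pipeline
#'
#' simulate -> project (Poisson) -> reconstruct NAC -> preprocess -> train ->
#' predict -> rebuild pseudo-CT -> mu-map -> reconstruct with attenuation
#' correction -> evaluate. With \code{oracle_pseudo_ct = TRUE} the network
#' is skipped and the true CT stands in for the pseudo-CT, closing the loop:
#' the "deepAC" reconstruction is then bit-identical to CTAC.
#'
#' @param cfg a \code{\link{run_config}}
#' @param out_dir optional output directory for volumes, metrics and the run
#'   manifest
#' @param oracle_pseudo_ct replace the network pseudo-CT by the true CT
#' @param verbose log stage progress and the parameter defaults in use
#' @return list with \code{metrics}, \code{roi_report}, \code{curve},
#'   \code{per_subject} metrics and (when trained) the \code{network}
#' @export
full_run <- function(cfg, out_dir = NULL, oracle_pseudo_ct = FALSE,
                     verbose = FALSE) {
  t0 <- proc.time()[3]
  log_lines <- character()
  say <- function(...) {
    line <- sprintf("[%7.1fs] %s", proc.time()[3] - t0, sprintf(...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  say("config: mode=%s n_train=%d n_test=%d grid=%d target=%sx%s",
      cfg$mode, cfg$n_train, cfg$n_test, cfg$phantom$grid_size,
      cfg$preprocess$target_matrix[1], cfg$preprocess$target_matrix[2])
  say("defaults: mu_water=0.096/cm osem=%dit/%dsub filter=%gmm lr=%g batch=%d",
      cfg$recon$n_iterations, cfg$recon$n_subsets,
      cfg$recon$post_filter_fwhm, cfg$train$learning_rate,
      cfg$train$batch_size)
  say("defaults: count_scale=%g eps=%g angles=%d epochs=%d crop=%g/%dpx thresholds=bone>300/air<-400",
      cfg$count_scale, cfg$recon$epsilon, cfg$geometry$n_angles,
      cfg$train$n_epochs, cfg$preprocess$crop_threshold,
      cfg$preprocess$crop_margin)

  coh <- simulate_cohort(cfg)
  say("simulated %d phantoms", length(coh$phantoms))

  scans <- lapply(seq_along(coh$phantoms), function(i)
    scan_phantom(coh$phantoms[[i]], cfg, i - 1L))
  say("projected + reconstructed NAC for %d phantoms", length(scans))

  train_ix <- which(coh$split == "train")
  test_ix <- which(coh$split == "test")

  trained <- NULL
  curve <- NULL
  if (!oracle_pseudo_ct) {
    pairs <- do.call(c, lapply(train_ix, function(i)
      build_slice_pairs(scans[[i]]$nac, coh$phantoms[[i]]$ct, cfg$preprocess,
                        source_id = sprintf("phantom_%03d", i - 1L))))
    say("built %d training slice pairs", length(pairs))
    net <- initialize_weights(build_network(cfg$network,
                                            cfg$preprocess$target_matrix),
                              seed = substream_seed(cfg$master_seed, "init"))
    say("network: %d trainable parameters", count_parameters(net))
    fit <- train_network(net, pairs, cfg$train, verbose = verbose)
    trained <- fit$network
    curve <- fit$curve
    say("trained %d epochs; best epoch %d (loss %.5g)",
        length(curve$loss), curve$best_epoch, min(curve$loss))
  } else {
    say("oracle mode: pseudo-CT := true CT, training skipped")
  }

  per <- lapply(test_ix, function(i) {
    ph <- coh$phantoms[[i]]; sc <- scans[[i]]
    pseudo <- if (oracle_pseudo_ct) ph$ct
    else synthesize_pseudo_ct(trained, sc$nac, cfg$preprocess)
    ctac <- reconstruct_osem(sc$sino, sc$mu_true, cfg$recon,
                             provenance = "CTAC")
    deepac <- reconstruct_osem(sc$sino, ct_to_mu(pseudo), cfg$recon,
                               provenance = "deepAC")
    lab_t <- discretize_ct(ph$ct)
    lab_p <- discretize_ct(pseudo)
    head <- head_mask_from_tissue(ph$ct$tissue)
    brain <- ph$activity$label_map > 0
    em_deep <- error_map(deepac, ctac, mask = brain)
    em_nac <- error_map(sc$nac, ctac, mask = brain)
    list(index = i, pseudo = pseudo, ctac = ctac, deepac = deepac,
         nac = sc$nac, labels = ph$activity$label_map,
         dice_soft = dice(lab_t, lab_p, "soft"),
         dice_bone = dice(lab_t, lab_p, "bone"),
         dice_air_cavity = dice(lab_t, lab_p, "air", mask = head),
         mae_hu = mae(pseudo, ph$ct, mask = head),
         mae_baseline_hu = mae(array(40, dim(head)), ph$ct, mask = head),
         pet_abs_err_deepac = mean(em_deep$abs_err[em_deep$mask]),
         pet_abs_err_nac = mean(em_nac$abs_err[em_nac$mask]))
  })
  say("evaluated %d held-out phantoms", length(per))

  avg <- function(f) mean(vapply(per, `[[`, numeric(1), f))
  metrics <- list(
    dice_soft = avg("dice_soft"), dice_bone = avg("dice_bone"),
    dice_air_cavity = avg("dice_air_cavity"),
    mae_hu = avg("mae_hu"), mae_baseline_hu = avg("mae_baseline_hu"),
    pet_abs_err_deepac_pct = avg("pet_abs_err_deepac"),
    pet_abs_err_nac_pct = avg("pet_abs_err_nac"),
    nac_to_deepac_error_ratio = avg("pet_abs_err_nac") /
      max(avg("pet_abs_err_deepac"), .Machine$double.eps))

  roi_report <- roi_statistics(lapply(per, `[[`, "deepac"),
                               lapply(per, `[[`, "ctac"),
                               lapply(per, `[[`, "labels"))
  say("headline: dice soft/bone/air = %.3f/%.3f/%.3f mae=%.1fHU err=%.2f%%",
      metrics$dice_soft, metrics$dice_bone, metrics$dice_air_cavity,
      metrics$mae_hu, metrics$pet_abs_err_deepac_pct)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    first <- per[[1]]
    sp <- coh$phantoms[[first$index]]$ct$spacing
    write_volume(first$pseudo$voxels, sp, file.path(out_dir, "pseudo_ct.nii.gz"))
    write_volume(first$ctac$voxels, sp, file.path(out_dir, "pet_ctac.nii.gz"))
    write_volume(first$deepac$voxels, sp, file.path(out_dir, "pet_deepac.nii.gz"))
    write_volume(first$nac$voxels, sp, file.path(out_dir, "pet_nac.nii.gz"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(roi_report, file.path(out_dir, "roi_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(curve))
      utils::write.table(data.frame(epoch = seq_along(curve$loss),
                                    loss = curve$loss),
                         file.path(out_dir, "loss_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(metrics = metrics, roi_report = roi_report, curve = curve,
       per_subject = lapply(per, function(p)
         p[c("dice_soft", "dice_bone", "dice_air_cavity", "mae_hu",
             "pet_abs_err_deepac", "pet_abs_err_nac")]),
       network = trained, log = log_lines)
}
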