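# End-to-end pipelines: phantom generation -> preprocessing -> training
# -> scoring -> segmentation -> evaluation, with reproducible seeds and
# artifacts written under a run directory.

#' Full run configuration
#'
#' Builds the fully-resolved configuration of an end-to-end run from a
#' scale preset plus per-module overrides. Thresholds t_ar, t_al and
#' t_un are calibrated on the healthy validation split by default
#' (percentiles of pooled per-cell score values); fixed values can be
#' supplied instead.
#'
#' @param preset `"desk"` (128-px phantoms, small models) or `"paper"`
#'   (full-scale settings).
#' @param run_id Name of the run directory.
#' @param output_dir Parent directory for run artifacts.
#' @param global_seed Integer; seeds every stage deterministically.
#' @param n_healthy,n_diseased Phantom counts for the generated dataset.
#' @param phantom,vqvae,ar,unet,post Named lists of overrides forwarded
#'   to [phantom_config()], [vqvae_config()], [ar_config()],
#'   [unet_config()] and [postprocess_config()].
#' @param t_ar_percentile Validation percentile defining t_ar
#'   (default 95).
#' @param t_al Fixed ALM threshold, or `NULL` to calibrate.
#' @param t_un Fixed uncertainty threshold, or `NULL` to calibrate.
#' @param calibration_percentile Validation percentile used when
#'   calibrating t_al / t_un (default 99: pixels beyond the healthy
#'   99th percentile are flagged).
#' @param enhance_segmentation Apply vesselness enhancement on the
#'   U-Net segmentation path (classification paths always use raw
#'   images). Off by default: at desk scale the ridge filter suppresses
#'   the capillary-mesh texture the segmenter relies on, and held-out
#'   vessel Dice is higher without it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "paper"),
                       run_id = "run",
                       output_dir = tempfile("octanomaly_"),
                       global_seed = 1L,
                       n_healthy = 200L,
                       n_diseased = 40L,
                       phantom = list(),
                       vqvae = list(),
                       ar = list(),
                       unet = list(),
                       post = list(),
                       t_ar_percentile = 95,
                       t_al = NULL,
                       t_un = NULL,
                       calibration_percentile = 99,
                       enhance_segmentation = FALSE) {
  preset <- match.arg(preset)
  seed <- as.integer(global_seed)
  image_size <- if (preset == "desk") 128L else 480L
  ph <- do.call(phantom_config, utils::modifyList(
    list(image_size = image_size, rng_seed = seed), phantom))
  image_size <- ph$image_size   # a phantom override drives every stage
  vq <- do.call(vqvae_config, utils::modifyList(
    list(preset = preset, image_size = image_size, rng_seed = seed + 1L),
    vqvae))
  arc <- do.call(ar_config, utils::modifyList(
    list(preset = preset, codebook_k = vq$codebook_k,
         rng_seed = seed + 2L), ar))
  un <- do.call(unet_config, utils::modifyList(
    list(preset = preset, rng_seed = seed + 3L), unet))
  pp <- do.call(postprocess_config, utils::modifyList(
    list(reference_size = 480L), post))
  pre_cls <- preprocess_config(resize_to = if (preset == "desk")
                               image_size else 512L,
                               crop_to = image_size, enhance = FALSE)
  pre_seg <- preprocess_config(resize_to = if (preset == "desk")
                               image_size else 512L,
                               crop_to = image_size, enhance = TRUE,
                               vesselness_scales = c(1, 2))
  structure(list(preset = preset, run_id = run_id,
                 output_dir = output_dir, global_seed = seed,
                 n_healthy = as.integer(n_healthy),
                 n_diseased = as.integer(n_diseased),
                 phantom = ph, vqvae = vq, ar = arc, unet = un,
                 post = pp, pre_cls = pre_cls, pre_seg = pre_seg,
                 t_ar_percentile = t_ar_percentile, t_al = t_al,
                 t_un = t_un,
                 calibration_percentile = calibration_percentile,
                 enhance_segmentation = isTRUE(enhance_segmentation)),
            class = "run_config")
}

run_dir <- function(cfg) file.path(cfg$output_dir, cfg$run_id)

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Freeze the fully-resolved config next to the run artifacts.
freeze_config <- function(cfg, dir) {
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  yaml::write_yaml(plain, file.path(dir, "config.yaml"))
}

#' Generate (or reuse) the phantom dataset of a run
#'
#' Writes the dataset under `<output_dir>/<run_id>/dataset`; an existing
#' manifest is reused so the two pipelines of one run share their data.
#'
#' @param cfg A [run_config()].
#' @return The dataset manifest.
#' @export
prepare_dataset <- function(cfg) {
  ddir <- file.path(run_dir(cfg), "dataset")
  mpath <- file.path(ddir, "MANIFEST.csv")
  if (file.exists(mpath)) return(read_manifest(mpath))
  stage("generate", make_dataset(cfg$n_healthy, cfg$n_diseased,
                                 cfg$phantom, ddir))
}

load_standardized <- function(manifest, idx, pre) {
  lapply(idx, function(i)
    standardize(load_image(manifest_path(manifest, "image", i)), pre))
}

write_scores_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

summarize_run <- function(dir, scan_report, pixel_report, extra = list()) {
  pixel <- if (is.null(pixel_report)) list() else
    as.list(stats::setNames(pixel_report$summary$mean,
                            pixel_report$summary$metric))
  summary <- c(list(
    scan = scan_report[c("auroc", "average_precision", "f1_at_youden",
                         "operating_threshold")],
    pixel = pixel),
    extra)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary
}

# Pixel-threshold calibration on the validation split. Candidate
# thresholds are percentiles of pooled healthy-validation score cells;
# when the validation split holds diseased scans with anomaly masks,
# the candidate maximising their mean Dice is chosen (thresholds are
# tuned on validation data, never on the test split). Without diseased
# validation scans the `fallback_percentile` is used directly.
calibrate_pixel_threshold <- function(healthy_cells, fallback_percentile,
                                      score_map, manifest, post,
                                      percentiles = c(90, 95, 97.5, 99,
                                                      99.5),
                                      val_subset = NULL) {
  fallback <- calibrate_t_ar(healthy_cells, fallback_percentile)
  val_d <- if (is.null(val_subset)) {
    which(manifest$split == "val" & manifest$label == "diseased")
  } else {
    val_subset
  }
  if (length(val_d) == 0) return(fallback)
  maps <- lapply(val_d, score_map)
  gts <- lapply(val_d, function(i) {
    (load_image(manifest_path(manifest, "anomaly_mask", i)) > 0.5) * 1
  })
  cand <- unique(c(vapply(percentiles, function(p)
    calibrate_t_ar(healthy_cells, p), numeric(1)), fallback))
  mean_dice <- vapply(cand, function(th) {
    mean(mapply(function(m, g) {
      dice(refine(binarize(m, th), utils::modifyList(
        post, list(threshold = th))), g)
    }, maps, gts))
  }, numeric(1))
  cand[which.max(mean_dice)]
}

#' Run the VQ-VAE + AR anomaly-detection pipeline
#'
#' Generates phantoms, trains the VQ-VAE on the healthy train split,
#' trains the AR prior on its latents, calibrates t_ar (scan threshold)
#' and t_al (ALM pixel threshold) on healthy validation scans, then
#' evaluates scan-wise scores (AUROC / AP / F1 at the Youden point) on
#' the test split and pixel-wise ALM segmentations against the injected
#' anomaly masks of diseased test images.
#'
#' @param cfg A [run_config()].
#' @param verbose Print training progress.
#' @return A list with `scan_report`, `pixel_report`, `thresholds`,
#'   `scores` (data.frame), `models` and `dir`.
#' @export
run_vqvae_ar_pipeline <- function(cfg, verbose = FALSE) {
  dir.create(run_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  freeze_config(cfg, run_dir(cfg))
  manifest <- prepare_dataset(cfg)
  pre <- cfg$pre_cls

  tr_idx <- which(manifest$split == "train")
  if (length(tr_idx) == 0) {
    stop("pipeline stage 'train-vqvae' failed: train split is empty",
         call. = FALSE)
  }
  train_imgs <- stage("standardize",
                      load_standardized(manifest, tr_idx, pre))
  vq <- stage("train-vqvae", {
    validate_manifest(manifest)
    if (any(manifest$label[tr_idx] == "diseased")) {
      stop("diseased image in train split")
    }
    train_vqvae(NULL, cfg$vqvae, images = train_imgs, verbose = verbose)
  })
  latents <- stage("encode", lapply(train_imgs, function(x)
    quantize(vqvae_encode(x, vq), vq$codebook)$indices))
  val_idx <- which(manifest$split == "val" & manifest$label == "healthy")
  val_imgs <- load_standardized(manifest, val_idx, pre)
  val_lat <- lapply(val_imgs, function(x)
    quantize(vqvae_encode(x, vq), vq$codebook)$indices)
  arm <- stage("train-ar", train_ar(latents, cfg$ar,
                                    val_latents = val_lat,
                                    verbose = verbose))

  val_nll <- stage("calibrate", lapply(val_lat, nll_map, model = arm))
  t_ar <- calibrate_t_ar(unlist(val_nll), cfg$t_ar_percentile)
  t_al <- if (is.null(cfg$t_al)) {
    val_alm_cells <- unlist(lapply(val_imgs, function(x)
      alm_map(x, vq, upscale = FALSE)))
    stage("calibrate", calibrate_pixel_threshold(
      val_alm_cells, cfg$calibration_percentile,
      score_map = function(i) alm_map(standardize(load_image(
        manifest_path(manifest, "image", i)), pre), vq),
      manifest = manifest, post = cfg$post))
  } else {
    cfg$t_al
  }

  te_idx <- which(manifest$split == "test")
  te_imgs <- load_standardized(manifest, te_idx, pre)
  te_q <- lapply(te_imgs, function(x)
    quantize(vqvae_encode(x, vq), vq$codebook))
  scores <- stage("score", data.frame(
    image = manifest$image[te_idx],
    label = as.integer(manifest$label[te_idx] == "diseased"),
    scan_score = vapply(te_q, function(q) {
      scan_score(nll_map(q$indices, arm), t_ar)
    }, numeric(1))))
  scan_report <- stage("evaluate",
                       scan_eval_report(scores$scan_score, scores$label))

  dis_pos <- which(manifest$label[te_idx] == "diseased")
  pixel_report <- NULL
  if (length(dis_pos) > 0) {
    preds <- list(); gts <- list()
    for (j in seq_along(dis_pos)) {
      i <- te_idx[dis_pos[j]]
      amask <- standardize(load_image(
        manifest_path(manifest, "anomaly_mask", i)),
        preprocess_config(resize_to = pre$resize_to,
                          crop_to = pre$crop_to)) > 0.5
      up <- alignment_loss_map_upscaled(te_q[[dis_pos[j]]]$alm,
                                        nrow(te_imgs[[dis_pos[j]]]))
      seg <- refine(binarize(up, t_al),
                    utils::modifyList(cfg$post, list(threshold = t_al)))
      preds[[j]] <- seg
      gts[[j]] <- amask * 1
    }
    pixel_report <- stage("evaluate", pixel_eval_report(preds, gts))
  }

  out <- run_dir(cfg)
  write_scores_csv(scores, file.path(out, "scan_scores_vqvae_ar.csv"))
  if (!is.null(pixel_report)) {
    utils::write.csv(pixel_report$per_image,
                     file.path(out, "pixel_metrics_vqvae_ar.csv"),
                     row.names = FALSE)
  }
  summary <- summarize_run(out, scan_report, pixel_report,
                           extra = list(t_ar = t_ar, t_al = t_al))
  list(scan_report = scan_report, pixel_report = pixel_report,
       thresholds = list(t_ar = t_ar, t_al = t_al), scores = scores,
       models = list(vqvae = vq, ar = arm), dir = out,
       summary = summary)
}

#' Run the Bayesian U-Net epistemic-uncertainty pipeline
#'
#' Trains the dropout U-Net on healthy train images (vesselness-enhanced
#' on the segmentation path) against their vessel masks, computes
#' Monte-Carlo-dropout uncertainty maps for validation and test scans,
#' calibrates t_un on healthy validation uncertainty, and evaluates
#' scan-wise scores plus pixel-wise anomaly segmentations; also reports
#' the vessel-segmentation Dice on held-out healthy phantoms.
#'
#' @param cfg A [run_config()].
#' @param verbose Print training progress.
#' @return A list with `scan_report`, `pixel_report`, `vessel_dice`,
#'   `uncertainty_inside_gt_outside`, `thresholds`, `scores`, `model`,
#'   `dir`.
#' @export
run_bayes_unet_pipeline <- function(cfg, verbose = FALSE) {
  dir.create(run_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  freeze_config(cfg, run_dir(cfg))
  manifest <- prepare_dataset(cfg)
  if (cfg$unet$dropout_p <= 0) {
    stop("pipeline stage 'mc-predict' failed: dropout_p is 0, epistemic ",
         "uncertainty is undefined", call. = FALSE)
  }
  pre <- cfg$pre_cls
  enh <- if (cfg$enhance_segmentation) cfg$pre_seg else NULL
  prep_seg <- function(img) {
    x <- standardize(img, pre)
    if (!is.null(enh)) vesselness_enhance(x, enh) else x
  }

  tr_idx <- which(manifest$split == "train" &
                    manifest$label == "healthy")
  if (length(tr_idx) == 0) {
    stop("pipeline stage 'train-unet' failed: train split is empty",
         call. = FALSE)
  }
  tr_imgs <- stage("standardize", lapply(tr_idx, function(i)
    prep_seg(load_image(manifest_path(manifest, "image", i)))))
  tr_masks <- lapply(tr_idx, function(i)
    load_image(manifest_path(manifest, "vessel_mask", i)) > 0.5)
  un <- stage("train-unet",
              train_unet(NULL, cfg$unet, images = tr_imgs,
                         masks = tr_masks, verbose = verbose))

  umap_of <- function(i, seed_off) {
    img <- prep_seg(load_image(manifest_path(manifest, "image", i)))
    st <- mc_predict(img, un, n = cfg$unet$n_mc,
                     seed = cfg$global_seed + seed_off)
    epistemic_uncertainty(st)
  }

  t_un <- if (is.null(cfg$t_un)) {
    # Monte-Carlo maps are the expensive step, so calibration uses at
    # most 10 healthy + 10 diseased validation scans
    val_idx <- utils::head(which(manifest$split == "val" &
                                   manifest$label == "healthy"), 10L)
    val_u <- stage("calibrate", lapply(seq_along(val_idx), function(j)
      umap_of(val_idx[j], 1000L + j)))
    val_d <- utils::head(which(manifest$split == "val" &
                                 manifest$label == "diseased"), 10L)
    umap_cache <- new.env()
    stage("calibrate", calibrate_pixel_threshold(
      unlist(val_u), cfg$calibration_percentile,
      score_map = function(i) {
        key <- as.character(i)
        if (is.null(umap_cache[[key]])) {
          umap_cache[[key]] <- umap_of(i, 3000L + match(i, val_d))
        }
        umap_cache[[key]]
      },
      manifest = manifest, post = cfg$post, val_subset = val_d))
  } else {
    cfg$t_un
  }

  te_idx <- which(manifest$split == "test")
  umaps <- stage("mc-predict", lapply(seq_along(te_idx), function(j)
    umap_of(te_idx[j], 2000L + j)))
  scores <- data.frame(
    image = manifest$image[te_idx],
    label = as.integer(manifest$label[te_idx] == "diseased"),
    scan_score = vapply(umaps, scanwise_from_map, numeric(1),
                        threshold = t_un))
  scan_report <- stage("evaluate",
                       scan_eval_report(scores$scan_score, scores$label))

  # pixel-wise segmentation of diseased test scans + paired inside vs
  # outside uncertainty comparison
  dis_pos <- which(manifest$label[te_idx] == "diseased")
  pixel_report <- NULL
  inside_gt_outside <- NA_real_
  if (length(dis_pos) > 0) {
    preds <- list(); gts <- list(); inout <- logical(length(dis_pos))
    for (j in seq_along(dis_pos)) {
      i <- te_idx[dis_pos[j]]
      u <- umaps[[dis_pos[j]]]
      amask <- load_image(manifest_path(manifest, "anomaly_mask", i)) > 0.5
      preds[[j]] <- refine(binarize(u, t_un),
                           utils::modifyList(cfg$post,
                                             list(threshold = t_un)))
      gts[[j]] <- amask * 1
      inout[j] <- mean(u[amask]) > mean(u[!amask])
    }
    pixel_report <- stage("evaluate", pixel_eval_report(preds, gts))
    inside_gt_outside <- mean(inout)
  }

  # vessel segmentation quality on held-out healthy phantoms
  hte_idx <- which(manifest$split == "test" & manifest$label == "healthy")
  vessel_dice <- vapply(hte_idx, function(i) {
    img <- prep_seg(load_image(manifest_path(manifest, "image", i)))
    pred <- unet_predict(img, un) > 0.5
    gt <- load_image(manifest_path(manifest, "vessel_mask", i)) > 0.5
    dice(pred * 1, gt * 1)
  }, numeric(1))

  out <- run_dir(cfg)
  write_scores_csv(scores, file.path(out, "scan_scores_bayes_unet.csv"))
  if (!is.null(pixel_report)) {
    utils::write.csv(pixel_report$per_image,
                     file.path(out, "pixel_metrics_bayes_unet.csv"),
                     row.names = FALSE)
  }
  summary <- summarize_run(out, scan_report, pixel_report,
                           extra = list(t_un = t_un,
                                        vessel_dice = mean(vessel_dice),
                                        uncertainty_inside_gt_outside =
                                          inside_gt_outside))
  list(scan_report = scan_report, pixel_report = pixel_report,
       vessel_dice = mean(vessel_dice),
       uncertainty_inside_gt_outside = inside_gt_outside,
       thresholds = list(t_un = t_un), scores = scores, model = un,
       dir = out, summary = summary)
}
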