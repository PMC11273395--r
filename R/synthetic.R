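# Synthetic OCTA-like vessel phantoms.
#
# Healthy en face angiography projections are emulated as bright
# curvilinear vessel trees on a dark noisy background: each vessel is a
# bounded-curvature random walk stamped with a Gaussian cross-sectional
# intensity profile, with stochastic branching and an optional darker
# central disk imitating the foveal avascular zone. Anomalies mirror the
# lesion classes seen in diabetic retinopathy OCTA: capillary dropout
# (locally erased perfusion), neovascular tufts (a dense added tangle) and
# vessel tortuosity (a local non-smooth warp of the vessel course).

#' Configuration for the vessel phantom generator
#'
#' @param image_size Side length in pixels (square images). Default 128 is
#'   the desk-scale size; larger sizes (e.g. 480) are supported.
#' @param n_seed_vessels Number of primary vessels grown from random seeds.
#' @param branch_probability Per-step probability that a vessel spawns a
#'   side branch.
#' @param vessel_width_range Length-2 numeric, full width (in pixels) of
#'   the Gaussian vessel profile; per-vessel widths are drawn uniformly
#'   from this range.
#' @param background_noise_sigma Standard deviation of the additive
#'   background intensity noise.
#' @param capillary_contrast Peak intensity of the fine capillary-mesh
#'   texture filling the perfused field between the larger vessels (en
#'   face full projections show a dense reticular capillary plexus, not
#'   a dark void); 0 disables the mesh.
#' @param fov_margin Margin in pixels kept free of vessel seeds; vessels
#'   terminate when they leave the field of view.
#' @param faz Logical; imitate the foveal avascular zone with a darker
#'   central disk (cosmetic).
#' @param faz_radius Radius of the FAZ disk in pixels; default
#'   `image_size / 10`.
#' @param rng_seed Integer seed; identical configurations with identical
#'   seeds produce bit-identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           n_seed_vessels = 10L,
                           branch_probability = 0.02,
                           vessel_width_range = c(1.6, 3.2),
                           background_noise_sigma = 0.03,
                           capillary_contrast = 0.35,
                           fov_margin = 4L,
                           faz = TRUE,
                           faz_radius = NULL,
                           rng_seed = 1L) {
  stopifnot_scalar(image_size, "image_size")
  if (image_size < 32) stop("image_size must be at least 32", call. = FALSE)
  stopifnot_scalar(branch_probability, "branch_probability")
  if (branch_probability < 0 || branch_probability > 1) {
    stop("branch_probability must lie in [0, 1]", call. = FALSE)
  }
  if (length(vessel_width_range) != 2L || any(vessel_width_range <= 0) ||
      diff(vessel_width_range) < 0) {
    stop("vessel_width_range must be positive and ordered", call. = FALSE)
  }
  if (background_noise_sigma < 0) {
    stop("background_noise_sigma must be nonnegative", call. = FALSE)
  }
  if (capillary_contrast < 0 || capillary_contrast > 1) {
    stop("capillary_contrast must lie in [0, 1]", call. = FALSE)
  }
  if (2 * fov_margin >= image_size) {
    stop("image_size too small to place fov_margin", call. = FALSE)
  }
  if (is.null(faz_radius)) faz_radius <- image_size / 10
  structure(list(
    image_size = as.integer(image_size),
    n_seed_vessels = as.integer(n_seed_vessels),
    branch_probability = branch_probability,
    vessel_width_range = vessel_width_range,
    background_noise_sigma = background_noise_sigma,
    capillary_contrast = capillary_contrast,
    fov_margin = as.integer(fov_margin),
    faz = isTRUE(faz),
    faz_radius = faz_radius,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_config")
}

#' Read or write a phantom configuration as YAML
#'
#' @param cfg A [phantom_config()] object.
#' @param path File path.
#' @return `read_phantom_config` returns a `phantom_config`;
#'   `write_phantom_config` returns `path` invisibly.
#' @export
write_phantom_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  do.call(phantom_config, yaml::read_yaml(path))
}

# Stamp a Gaussian blob of width sigma and amplitude amp at (ci, cj) onto
# the accumulators held in env `acc` (ink = intensity, prof = profile
# relative to the per-vessel peak, used for the half-peak vessel mask).
stamp_blob <- function(acc, ci, cj, sigma, amp, nr, nc = nr) {
  r <- ceiling(2.5 * sigma)
  i0 <- max(1L, floor(ci) - r); i1 <- min(nr, floor(ci) + r + 1L)
  j0 <- max(1L, floor(cj) - r); j1 <- min(nc, floor(cj) + r + 1L)
  if (i0 > i1 || j0 > j1) return(invisible(NULL))
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  acc$ink[ii, jj] <- pmax(acc$ink[ii, jj], amp * g)
  acc$prof[ii, jj] <- pmax(acc$prof[ii, jj], g)
  invisible(NULL)
}

#' Generate a healthy OCTA-like vessel phantom
#'
#' Grows `n_seed_vessels` vessels as bounded-curvature random walks with
#' stochastic branching, stamps each with a Gaussian cross-sectional
#' profile, and adds background noise (plus a darker central disk when
#' `faz` is enabled). The vessel mask marks pixels whose vessel-profile
#' contribution exceeds half the per-vessel peak profile.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `image` (numeric matrix in `[0, 1]`) and
#'   `vessel_mask` (logical matrix).
#' @export
generate_vessel_tree <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  S <- config$image_size
  m <- config$fov_margin
  with_seed(config$rng_seed, {
    acc <- new.env(parent = emptyenv())
    acc$ink <- matrix(0, S, S)
    acc$prof <- matrix(0, S, S)
    if (config$n_seed_vessels > 0) {
      # each queued segment: start position, heading, width, amplitude
      queue <- vector("list", 0L)
      for (v in seq_len(config$n_seed_vessels)) {
        queue[[length(queue) + 1L]] <- list(
          pos = stats::runif(2, m + 1, S - m),
          heading = stats::runif(1, 0, 2 * pi),
          width = stats::runif(1, config$vessel_width_range[1],
                               config$vessel_width_range[2]),
          amp = stats::runif(1, 0.7, 1.0),
          steps = round(stats::runif(1, 1.2 * S, 2.5 * S)))
      }
      max_segments <- 6L * config$n_seed_vessels
      n_segments <- 0L
      step_len <- 0.7
      while (length(queue) > 0 && n_segments < max_segments) {
        seg <- queue[[1L]]; queue[[1L]] <- NULL
        n_segments <- n_segments + 1L
        pos <- seg$pos; heading <- seg$heading
        sigma <- seg$width / 2
        for (s in seq_len(seg$steps)) {
          heading <- heading +
            max(-0.25, min(0.25, stats::rnorm(1, 0, 0.08)))
          pos <- pos + step_len * c(cos(heading), sin(heading))
          if (any(pos < m + 1) || any(pos > S - m)) break
          stamp_blob(acc, pos[1], pos[2], sigma, seg$amp, S)
          if (stats::runif(1) < config$branch_probability &&
              length(queue) + n_segments < max_segments) {
            queue[[length(queue) + 1L]] <- list(
              pos = pos,
              heading = heading + sample(c(-1, 1), 1) *
                stats::runif(1, 0.4, 0.9),
              width = max(config$vessel_width_range[1], seg$width * 0.8),
              amp = seg$amp * 0.9,
              steps = round(seg$steps / 2))
          }
        }
      }
    }
    vessel_mask <- acc$prof > 0.5
    img <- acc$ink
    if (config$capillary_contrast > 0) {
      # fine reticular capillary plexus: band-pass filtered noise fills
      # the perfused field between the larger vessels
      mesh <- matrix(stats::rnorm(S * S), S, S)
      mesh <- gaussian_smooth(mesh, 0.8) - gaussian_smooth(mesh, 2)
      mesh <- rescale01(mesh)
      img <- pmax(img, config$capillary_contrast * mesh)
    }
    if (config$faz) {
      ctr <- (S + 1) / 2
      d2 <- outer((seq_len(S) - ctr)^2, (seq_len(S) - ctr)^2, `+`)
      img <- img * (1 - 0.8 * exp(-d2 / (2 * config$faz_radius^2)))
    }
    noise <- 0.06 + stats::rnorm(S * S, 0, config$background_noise_sigma)
    img <- clip01(img + matrix(noise, S, S))
    list(image = img, vessel_mask = vessel_mask)
  })
}

#' Specification of an injected anomaly
#'
#' @param kind One of `"dropout"` (capillary non-perfusion: vessel signal
#'   attenuated toward background), `"tuft"` (neovascular tuft: a dense
#'   bright tangle added) or `"tortuosity"` (local non-smooth warp of the
#'   vessel course).
#' @param center Length-2 numeric, pixel coordinates (row, column) of the
#'   region center.
#' @param radius Region radius in pixels; the circular region must lie
#'   fully inside the image.
#' @param severity Effect strength in `[0, 1]`.
#' @param rng_seed Integer seed for the stochastic anomaly kinds.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind, center, radius, severity = 0.8,
                         rng_seed = 1L) {
  kind <- match.arg(kind, c("dropout", "tuft", "tortuosity"))
  stopifnot_scalar(radius, "radius")
  stopifnot_scalar(severity, "severity")
  if (severity < 0 || severity > 1) {
    stop("severity must lie in [0, 1]", call. = FALSE)
  }
  if (length(center) != 2L) stop("center must be length 2", call. = FALSE)
  structure(list(kind = kind, center = as.numeric(center), radius = radius,
                 severity = severity, rng_seed = as.integer(rng_seed)),
            class = "anomaly_spec")
}

region_disk <- function(center, radius, nr, nc) {
  d2 <- outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, `+`)
  d2 <= radius^2
}

#' Inject an anomaly into a phantom
#'
#' Modifies the image only inside the circular region declared by `spec`;
#' pixels outside the region are bit-identical to the input. The returned
#' anomaly mask marks exactly the region.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param vessel_mask Logical matrix of the same size (used to estimate
#'   the background level for capillary dropout).
#' @param spec An [anomaly_spec()].
#' @return A list with elements `image` and `anomaly_mask`.
#' @export
inject_anomaly <- function(image, vessel_mask, spec) {
  stopifnot(inherits(spec, "anomaly_spec"))
  nr <- nrow(image); nc <- ncol(image)
  ctr <- spec$center; rad <- spec$radius
  if (ctr[1] - rad < 1 || ctr[1] + rad > nr ||
      ctr[2] - rad < 1 || ctr[2] + rad > nc) {
    stop("anomaly region must lie fully inside the image", call. = FALSE)
  }
  region <- region_disk(ctr, rad, nr, nc)
  out <- image
  with_seed(spec$rng_seed, {
    if (spec$kind == "dropout") {
      if (spec$severity > 0) {   # severity 0 is an exact no-op
        # non-perfusion reads as a dark signal void, so attenuate toward
        # the darkest background level (5th percentile), not the median
        # of the (capillary-bright) perfused field
        bg <- if (any(!vessel_mask)) {
          stats::quantile(image[!vessel_mask], 0.05, names = FALSE)
        } else {
          0
        }
        out[region] <- bg + (1 - spec$severity) * (image[region] - bg)
      }
    } else if (spec$kind == "tuft") {
      # dense tangle: many short high-intensity random strokes confined
      # to the inner 80% of the region
      acc <- new.env(parent = emptyenv())
      acc$ink <- matrix(0, nr, nc)
      acc$prof <- matrix(0, nr, nc)  # unused here; stamp_blob updates both
      n_strokes <- max(6L, round(3 * rad))
      for (s in seq_len(n_strokes)) {
        ang <- stats::runif(1, 0, 2 * pi)
        r0 <- stats::runif(1, 0, 0.6 * rad)
        pos <- ctr + r0 * c(cos(ang), sin(ang))
        heading <- stats::runif(1, 0, 2 * pi)
        for (t in seq_len(round(2 * rad))) {
          heading <- heading + stats::rnorm(1, 0, 0.5)
          cand <- pos + 0.7 * c(cos(heading), sin(heading))
          if (sqrt(sum((cand - ctr)^2)) > 0.8 * rad) {
            heading <- heading + pi
            next
          }
          pos <- cand
          stamp_blob(acc, pos[1], pos[2], 0.8, 1, nr, nc)
        }
      }
      add <- spec$severity * acc$ink[seq_len(nr), seq_len(nc)]
      out[region] <- clip01(image[region] + add[region])
      # guarantee a strict intensity increase for severity > 0 even where
      # clipping saturates
      if (spec$severity > 0 && sum(out[region]) <= sum(image[region])) {
        out[region] <- clip01(image[region] * (1 - 0.5 * spec$severity) +
                                add[region])
      }
    } else {  # tortuosity
      # smooth sinusoidal displacement field, tapered to zero at the
      # region boundary so that sampling never leaves the region
      idx <- which(region, arr.ind = TRUE)
      di <- idx[, 1] - ctr[1]
      dj <- idx[, 2] - ctr[2]
      r <- sqrt(di^2 + dj^2)
      taper <- (1 - (r / rad)^2)^2
      amp <- spec$severity * 0.25 * rad
      freq <- 2 * pi / (0.8 * rad)
      phase <- stats::runif(2, 0, 2 * pi)
      src_i <- idx[, 1] + amp * taper * sin(freq * dj + phase[1])
      src_j <- idx[, 2] + amp * taper * sin(freq * di + phase[2])
      out[region] <- bilinear_sample(image, src_i, src_j)
    }
  })
  list(image = out, anomaly_mask = region)
}

# Bilinear interpolation of matrix `img` at fractional (i, j) positions;
# positions are clamped to the image domain.
bilinear_sample <- function(img, i, j) {
  nr <- nrow(img); nc <- ncol(img)
  i <- pmin(pmax(i, 1), nr)
  j <- pmin(pmax(j, 1), nc)
  i0 <- pmin(floor(i), nr - 1); j0 <- pmin(floor(j), nc - 1)
  fi <- i - i0; fj <- j - j0
  v00 <- img[cbind(i0, j0)]
  v10 <- img[cbind(i0 + 1, j0)]
  v01 <- img[cbind(i0, j0 + 1)]
  v11 <- img[cbind(i0 + 1, j0 + 1)]
  (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
    (1 - fi) * fj * v01 + fi * fj * v11
}

#' Generate a phantom dataset with train/val/test manifest
#'
#' Healthy phantoms are split 80/10/10 across train/validation/test;
#' diseased phantoms (with one injected anomaly each) are split 50/50
#' between validation and test, so the train split is healthy-only.
#' Images and masks are written as 8-bit grayscale PNGs and the manifest
#' as a CSV with columns `image, vessel_mask, anomaly_mask, label, split`
#' (paths relative to `out_dir`).
#'
#' @param n_healthy Number of healthy phantoms (at least 10).
#' @param n_diseased Number of diseased phantoms.
#' @param config A [phantom_config()]; per-image seeds are derived from
#'   `config$rng_seed`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data.frame (invisibly carries `out_dir` in
#'   attribute `dir`).
#' @export
make_dataset <- function(n_healthy, n_diseased, config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_healthy < 10) stop("n_healthy must be at least 10", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  kinds <- c("dropout", "tuft", "tortuosity")
  S <- config$image_size
  scale <- S / 128
  rows <- list()
  with_seed(config$rng_seed, {
    seeds <- sample.int(2^30, n_healthy + n_diseased)
    anomaly_params <- if (n_diseased > 0) {
      data.frame(
        kind = kinds[(seq_len(n_diseased) - 1L) %% 3L + 1L],
        radius = stats::runif(n_diseased, 10, 22) * scale,
        severity = stats::runif(n_diseased, 0.6, 0.95))
    }
    healthy_split <- local({
      n_tr <- floor(0.8 * n_healthy)
      n_va <- floor(0.1 * n_healthy)
      sp <- c(rep("train", n_tr), rep("val", n_va),
              rep("test", n_healthy - n_tr - n_va))
      sample(sp)
    })
    diseased_split <- if (n_diseased > 0) {
      n_va <- floor(n_diseased / 2)
      sample(c(rep("val", n_va), rep("test", n_diseased - n_va)))
    } else character()
    for (i in seq_len(n_healthy)) {
      cfg_i <- config
      cfg_i$rng_seed <- seeds[i]
      ph <- generate_vessel_tree(cfg_i)
      img_p <- sprintf("healthy_%03d.png", i)
      msk_p <- sprintf("healthy_%03d_vessels.png", i)
      save_image(ph$image, file.path(out_dir, img_p))
      save_image(ph$vessel_mask, file.path(out_dir, msk_p))
      rows[[length(rows) + 1L]] <- data.frame(
        image = img_p, vessel_mask = msk_p, anomaly_mask = "",
        label = "healthy", split = healthy_split[i])
    }
    for (i in seq_len(n_diseased)) {
      cfg_i <- config
      cfg_i$rng_seed <- seeds[n_healthy + i]
      ph <- generate_vessel_tree(cfg_i)
      rad <- anomaly_params$radius[i]
      ctr <- stats::runif(2, rad + config$fov_margin + 1,
                          S - rad - config$fov_margin)
      sp <- anomaly_spec(anomaly_params$kind[i], ctr, rad,
                         anomaly_params$severity[i],
                         rng_seed = seeds[n_healthy + i] %% 2^20 + 1L)
      inj <- inject_anomaly(ph$image, ph$vessel_mask, sp)
      img_p <- sprintf("diseased_%03d.png", i)
      msk_p <- sprintf("diseased_%03d_vessels.png", i)
      ano_p <- sprintf("diseased_%03d_anomaly.png", i)
      save_image(inj$image, file.path(out_dir, img_p))
      save_image(ph$vessel_mask, file.path(out_dir, msk_p))
      save_image(inj$anomaly_mask, file.path(out_dir, ano_p))
      rows[[length(rows) + 1L]] <- data.frame(
        image = img_p, vessel_mask = msk_p, anomaly_mask = ano_p,
        label = "diseased", split = diseased_split[i])
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "MANIFEST.csv"),
                   row.names = FALSE)
  validate_manifest(manifest)
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Read a dataset manifest from CSV
#'
#' @param path Path to a `MANIFEST.csv` written by [make_dataset()].
#' @return The manifest data.frame with attribute `dir` set to the
#'   manifest's directory.
#' @export
read_manifest <- function(path) {
  manifest <- utils::read.csv(path, colClasses = "character")
  manifest$anomaly_mask[is.na(manifest$anomaly_mask)] <- ""
  validate_manifest(manifest)
  attr(manifest, "dir") <- dirname(path)
  manifest
}

#' Validate manifest invariants
#'
#' Checks that no diseased image sits in the train split, every diseased
#' record carries an anomaly mask, and splits partition the records.
#'
#' @param manifest A manifest data.frame.
#' @return `manifest`, invisibly; errors on violation.
#' @export
validate_manifest <- function(manifest) {
  need <- c("image", "vessel_mask", "anomaly_mask", "label", "split")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(manifest$split %in% c("train", "val", "test"))) {
    stop("splits must be train/val/test", call. = FALSE)
  }
  if (!all(manifest$label %in% c("healthy", "diseased"))) {
    stop("labels must be healthy/diseased", call. = FALSE)
  }
  bad <- manifest$label == "diseased" & manifest$split == "train"
  if (any(bad)) {
    stop("diseased images must not appear in the train split", call. = FALSE)
  }
  no_mask <- manifest$label == "diseased" & manifest$anomaly_mask == ""
  if (any(no_mask)) {
    stop("every diseased record needs an anomaly mask", call. = FALSE)
  }
  invisible(manifest)
}

# Resolve manifest paths against its directory.
manifest_path <- function(manifest, col, i) {
  file.path(attr(manifest, "dir"), manifest[[col]][i])
}
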