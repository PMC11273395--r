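# Vessel phantom generator: determinism, mask semantics, anomaly
# injection contracts and dataset manifests.

test_that("phantom generation is a pure function of config + seed", {
  cfg <- phantom_config(rng_seed = 11)
  a <- generate_vessel_tree(cfg)
  b <- generate_vessel_tree(cfg)
  expect_identical(a, b)
  c <- generate_vessel_tree(phantom_config(rng_seed = 12))
  expect_false(identical(a$image, c$image))
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("zero seed vessels give pure background and empty mask", {
  cfg <- phantom_config(n_seed_vessels = 0, rng_seed = 3)
  ph <- generate_vessel_tree(cfg)
  expect_false(any(ph$vessel_mask))
  expect_true(all(ph$image >= 0 & ph$image <= 1))
})

test_that("vessel-pixel fraction stays within the frozen bounds", {
  # bounds measured once over the default desk configuration and frozen
  fracs <- vapply(1:20, function(s) {
    mean(generate_vessel_tree(phantom_config(rng_seed = s))$vessel_mask)
  }, numeric(1))
  expect_true(all(fracs >= 0.05 & fracs <= 0.40))
})

test_that("configuration invariants are enforced", {
  expect_error(phantom_config(image_size = 16), "at least 32")
  expect_error(phantom_config(branch_probability = 1.5), "\\[0, 1\\]")
  expect_error(phantom_config(vessel_width_range = c(3, 1)), "ordered")
  expect_error(phantom_config(image_size = 40, fov_margin = 20),
               "fov_margin")
})

test_that("phantom config YAML round-trips", {
  cfg <- phantom_config(image_size = 64, n_seed_vessels = 5, rng_seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_phantom_config(cfg, path)
  expect_equal(read_phantom_config(path), cfg)
})

test_that("anomaly injection is local and honours severity limits", {
  ph <- generate_vessel_tree(phantom_config(rng_seed = 21))
  for (kind in c("dropout", "tuft", "tortuosity")) {
    sp <- anomaly_spec(kind, c(64, 64), 14, severity = 0.8, rng_seed = 5)
    out <- inject_anomaly(ph$image, ph$vessel_mask, sp)
    expect_identical(out$image[!out$anomaly_mask],
                     ph$image[!out$anomaly_mask])
    expect_true(any(out$anomaly_mask))
  }
  # severity 0 dropout: image untouched, mask still marks the region
  sp0 <- anomaly_spec("dropout", c(40, 80), 10, severity = 0)
  out0 <- inject_anomaly(ph$image, ph$vessel_mask, sp0)
  expect_identical(out0$image, ph$image)
  expect_true(any(out0$anomaly_mask))
})

test_that("dropout attenuates and tuft brightens the region", {
  ph <- generate_vessel_tree(phantom_config(rng_seed = 22))
  spd <- anomaly_spec("dropout", c(64, 64), 15, severity = 1)
  outd <- inject_anomaly(ph$image, ph$vessel_mask, spd)
  expect_lt(mean(outd$image[outd$anomaly_mask]),
            mean(ph$image[outd$anomaly_mask]))
  spt <- anomaly_spec("tuft", c(40, 90), 12, severity = 0.8)
  outt <- inject_anomaly(ph$image, ph$vessel_mask, spt)
  expect_gt(sum(outt$image[outt$anomaly_mask]),
            sum(ph$image[outt$anomaly_mask]))
})

test_that("anomaly spec validation rejects bad input", {
  ph <- generate_vessel_tree(phantom_config(rng_seed = 23))
  expect_error(anomaly_spec("melanoma", c(10, 10), 5), "arg")
  expect_error(inject_anomaly(ph$image, ph$vessel_mask,
                              anomaly_spec("dropout", c(5, 5), 10)),
               "inside")
})

test_that("make_dataset honours split fractions and invariants", {
  dir <- tempfile("ds_")
  cfg <- phantom_config(image_size = 48, n_seed_vessels = 4,
                        rng_seed = 42)
  man <- make_dataset(20, 10, cfg, dir)
  tab <- table(man$label, man$split)
  expect_equal(unname(tab["healthy", "train"]), 16)
  expect_equal(unname(tab["healthy", "val"]), 2)
  expect_equal(unname(tab["healthy", "test"]), 2)
  expect_equal(unname(tab["diseased", "val"]), 5)
  expect_equal(unname(tab["diseased", "test"]), 5)
  expect_false("train" %in% man$split[man$label == "diseased"])
  expect_true(all(man$anomaly_mask[man$label == "diseased"] != ""))

  # round trip through CSV keeps the invariants checkable
  man2 <- read_manifest(file.path(dir, "MANIFEST.csv"))
  expect_silent(validate_manifest(man2))
  expect_equal(nrow(man2), 30)

  # images on disk decode to [0,1] grayscale of the configured size
  img <- load_image(manifest_path(man2, "image", 1))
  expect_equal(dim(img), c(48, 48))

  # diseased images carry nonempty anomaly masks on disk
  di <- which(man2$label == "diseased")[1]
  am <- load_image(manifest_path(man2, "anomaly_mask", di))
  expect_gt(sum(am > 0.5), 0)
})

test_that("make_dataset with no diseased images is valid", {
  dir <- tempfile("ds_")
  cfg <- phantom_config(image_size = 48, n_seed_vessels = 3,
                        rng_seed = 1)
  man <- make_dataset(10, 0, cfg, dir)
  expect_false(any(man$label == "diseased"))
  expect_silent(validate_manifest(man))
})

test_that("validate_manifest rejects contract violations", {
  man <- data.frame(image = "a.png", vessel_mask = "b.png",
                    anomaly_mask = "", label = "diseased",
                    split = "train")
  expect_error(validate_manifest(man), "train split")
  man$split <- "val"
  expect_error(validate_manifest(man), "anomaly mask")
})
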