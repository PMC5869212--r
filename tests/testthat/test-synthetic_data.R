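test_that("the stratified design reproduces the survey layout", {
  d <- generate_design(generator_config(seed = 5))
  expect_equal(nrow(d), 180L)
  expect_equal(as.integer(table(d$green_space_type)), rep(20L, 9))
  cells <- table(d$green_space_type, d$size_class)
  expect_true(all(cells == 5L))
  expect_true(all(d$c_top >= 0 & d$c_top <= 1))
  expect_true(all(d$g >= 0 & d$g <= 100))
  # determinism
  expect_identical(d, generate_design(generator_config(seed = 5)))
  expect_false(identical(d$c_top, generate_design(generator_config(seed = 6))$c_top))
  expect_equal(nrow(generate_design(tiny_config())), 12L)
})

test_that("scene complexity endpoints hit the uniform and random MIG limits", {
  cfg <- generator_config(seed = 2, img_size = 512L)
  imgs0 <- generate_scene_images(site_row(c_top = 0, c_side = 0), cfg, 1L)
  m0 <- mean_information_gain(quantize_intensities(imgs0$TOP, M = 4))$mig
  expect_lt(m0, 0.05)
  imgs1 <- generate_scene_images(site_row(c_top = 1, c_side = 1), cfg, 1L)
  m1 <- mean_information_gain(quantize_intensities(imgs1$TOP, M = 4))$mig
  expect_gt(m1, 0.95)
  expect_length(imgs1, 5L)
  expect_named(imgs1, c("N", "E", "S", "W", "TOP"))
})

test_that("mean scene MIG increases strictly with latent complexity", {
  cfg <- generator_config(img_size = 64L)
  mean_mig <- vapply(c(0, 0.5, 1), function(cc) {
    mean(vapply(1:20, function(s) {
      cfg$seed <- 100L + s
      im <- generate_scene_images(site_row(c_top = cc, c_side = cc), cfg, 1L)
      mean_information_gain(quantize_intensities(im$TOP, M = cfg$M_analysis))$mig
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_mig) > 0))
})

test_that("vegetation profiles track the latent structure", {
  cfg <- generator_config(seed = 3)
  # bare site: almost no touches
  pr0 <- generate_vegetation_profiles(site_row(c_top = 0, c_side = 0, g = 0), cfg, 1L)
  expect_lt(sum(pr0$touches), 5)
  # fully complex canopy: canopy-class clutter near saturation (mean over sites)
  canopy_cl <- vapply(1:15, function(i) {
    pr <- generate_vegetation_profiles(site_row(c_top = 1, c_side = 0.5), cfg, i)
    mean(clutter_by_height(pr$touches)[c("10-15", ">15")])
  }, numeric(1))
  expect_gt(mean(canopy_cl), 0.7)
  expect_true(all(pr0$dbh >= 0))
})

test_that("realized field descriptors correlate with image-derived complexity", {
  study <- simulate_study(generator_config(seed = 11))
  d <- merge(study$mig, study$veg, by = "site_id")
  canopy_clutter <- rowMeans(d[, c("clutter_10_15", "clutter_15")])
  expect_gt(cor(d$mig_top, canopy_clutter), 0.3)
  expect_gt(cor(d$mig_top, d$canopy_cover), 0.3)
  expect_gt(cor(d$mig_top, d$tree_density), 0.3)
  expect_gt(cor(d$mig_sides, rowMeans(d[, c("clutter_0_0.5", "clutter_0.5_1")])), 0.3)
})

test_that("simulated surveys respect the design ledger", {
  cfg <- generator_config(seed = 4)
  design <- generate_design(cfg)
  sv <- generate_bat_surveys(design, cfg)
  expect_equal(nrow(sv$nights), 540L)
  expect_true(all(sv$records$night_index %in% 1:3))
  expect_true(all(sv$records$sequence_length_s > 0))
  expect_true(all(sv$records$species_label %in% species_config()$species))
  expect_true(all(sv$records$site_id %in% design$site_id))
  # deterministic given the configuration
  sv2 <- generate_bat_surveys(design, cfg)
  expect_identical(sv$records, sv2$records)
})

test_that("occupancy ranking shapes which species are common", {
  cfg <- generator_config(seed = 12)
  design <- generate_design(cfg)
  sv <- generate_bat_surveys(design, cfg)
  seen <- table(unlist(lapply(split(sv$records$species_label, sv$records$site_id), unique)))
  frac <- as.numeric(seen[c("P. pygmaeus", "N. noctula", "M. brandtii/M. mystacinus")]) / 180
  expect_gt(frac[1], 0.75)            # most widespread taxon
  expect_gt(frac[1], frac[2])         # ranking preserved on average
  expect_gt(frac[2], frac[3])
  rare <- setdiff(species_config()$species,
                  names(cfg$occupancy)[cfg$occupancy > 0.3])
  rare_frac <- as.numeric(seen[rare]) / 180
  expect_true(all(rare_frac < 0.35, na.rm = TRUE))
})

test_that("a null generator produces no spurious strong effects", {
  hits <- vapply(1:5, function(r) {
    cfg <- generator_config(seed = 400 + r, beta_migtop = 0, beta_ground = 0, tau = 0)
    design <- generate_design(cfg)
    sv <- generate_bat_surveys(design, cfg)
    resp <- site_response_table(sv$records, site_ids = design$site_id)
    d <- merge(design, resp, by = "site_id")
    d$y <- log1p(d$activity_total)
    d$z1 <- as.numeric(scale(d$c_top)); d$z2 <- as.numeric(scale(d$g))
    fit <- suppressWarnings(fit_activity_model(d, "y", c("z1", "z2")))
    any(abs(fit$coefficients$statistic[-1]) > 3)
  }, logical(1))
  expect_lte(mean(hits), 0.4)
})

test_that("the fixture bundle is complete, reproducible and loadable", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- tiny_config(seed = 9)
  t0 <- Sys.time()
  p1 <- make_fixture_bundle(cfg, dir1)
  p2 <- make_fixture_bundle(cfg, dir2)
  manifest <- read.csv(p1$manifest)
  expect_equal(nrow(manifest), 12L * 5L)
  expect_equal(as.integer(table(manifest$site_id)), rep(5L, 12))
  expect_setequal(unique(manifest$view), c("N", "E", "S", "W", "TOP"))
  # same seed, byte-identical tables
  for (f in c("design", "manifest", "touches", "surveys")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # the written images round-trip through the manifest loader
  tab <- site_mig_table(p1$manifest, M = 16, base_dir = dir1)
  expect_equal(nrow(tab), 12L)
  expect_true(all(is.finite(tab$mig_all)))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
})
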