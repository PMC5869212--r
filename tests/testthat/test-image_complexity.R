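test_that("value channel is the hue-independent max of RGB", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(value_channel_from_rgb(px(1, 1, 1)), matrix(1))
  expect_equal(value_channel_from_rgb(px(0, 0, 0)), matrix(0))
  expect_equal(value_channel_from_rgb(px(1, 0, 0)), matrix(1)) # red
  expect_equal(value_channel_from_rgb(px(1, 1, 0)), matrix(1)) # yellow
  # 8-bit integer channels are rescaled
  expect_equal(value_channel_from_rgb(array(c(128, 64, 32), c(1, 1, 3))),
               matrix(128 / 255))
  # shape preserved, alpha ignored
  img <- array(runif(5 * 7 * 4), dim = c(5, 7, 4))
  expect_identical(dim(value_channel_from_rgb(img)), c(5L, 7L))
  expect_error(value_channel_from_rgb(array(0, c(0, 3, 3))), "empty")
})

test_that("quantization bins intensities with a closed top edge", {
  q <- quantize_intensities(matrix(c(0, 1, 0.5, 0.999), 2), M = 2)
  expect_equal(as.vector(q), c(0L, 1L, 1L, 1L))
  expect_equal(as.vector(quantize_intensities(matrix(0.5), M = 256)), 128L)
  expect_equal(as.vector(quantize_intensities(matrix(0), M = 2)), 0L)
  expect_error(quantize_intensities(matrix(0.5), M = 0), "M must be")
  expect_error(quantize_intensities(matrix(1.5), M = 4), "\\[0, 1\\]")
  # every value below M
  f <- matrix(runif(100), 10)
  expect_true(all(quantize_intensities(f, M = 7) < 7))
})

test_that("entropy components match hand-computable cases and count invariants", {
  const <- quantize_intensities(matrix(0.3, 8, 8), M = 4)
  ec <- entropy_components(const)
  expect_identical(ec$h_marginal, 0)
  expect_identical(ec$h_joint, 0)

  # 2x2 anti-diagonal: two equally frequent pixel values, a single window
  qf <- quantize_intensities(matrix(c(0, 0.9, 0.9, 0), 2), M = 2)
  ec <- entropy_components(qf)
  expect_equal(ec$h_marginal, log(2))
  expect_equal(ec$h_joint, 0)
  expect_equal(ec$n_windows, 1L)
  expect_equal(ec$n_pixels, 4L)

  qf <- quantize_intensities(matrix(runif(30), 5, 6), M = 3)
  ec <- entropy_components(qf)
  expect_equal(ec$n_windows, 4L * 5L)
  expect_equal(ec$n_pixels, 30L)
  expect_lte(ec$n_configs, min(ec$n_windows, 3^4))
  expect_true(ec$h_marginal >= 0 && ec$h_marginal <= log(3) + 1e-12)
  expect_true(ec$h_joint >= 0 && ec$h_joint <= 4 * log(3) + 1e-12)

  expect_error(entropy_components(quantize_intensities(matrix(0.1, 1, 5), M = 2)),
               "at least 2x2")
})

test_that("entropies approach the analytic iid limits on a large image", {
  set.seed(42)
  qf <- quantize_intensities(iid_uniform_image(512), M = 2)
  ec <- entropy_components(qf)
  expect_equal(ec$h_marginal, log(2), tolerance = 1e-4)
  expect_equal(ec$h_joint, 4 * log(2), tolerance = 1e-3)
})

test_that("entropy components agree with brute-force enumeration on small images", {
  set.seed(101)
  for (i in 1:120) {
    v <- random_small_intensity()
    qf <- quantize_intensities(v, M = 2)
    fast <- entropy_components(qf)
    slow <- brute_force_entropies(unclass(qf))
    expect_equal(fast$h_marginal, slow$h_marginal, tolerance = 1e-12)
    expect_equal(fast$h_joint, slow$h_joint, tolerance = 1e-12)
  }
})

test_that("MIG is 0 for constant and periodic patterns, ~1 for random ones", {
  for (M in c(2, 16, 256)) {
    expect_identical(mean_information_gain(
      quantize_intensities(matrix(0.42, 16, 16), M = M))$mig, 0)
  }
  # checkerboard: both entropies equal log(2), perfectly ordered
  cb <- outer(1:64, 1:64, function(i, j) (i + j) %% 2 * 0.9)
  res <- mean_information_gain(quantize_intensities(cb, M = 2))
  expect_equal(res$mig, 0, tolerance = 1e-6)
  expect_equal(res$h_joint, log(2), tolerance = 1e-6)

  set.seed(7)
  res <- mean_information_gain(quantize_intensities(iid_uniform_image(512), M = 4))
  expect_equal(res$mig, 1, tolerance = 0.01)

  expect_error(mean_information_gain(quantize_intensities(matrix(0.5, 4, 4), M = 1)),
               "M must be >= 2")
})

test_that("MIG is invariant to the logarithm base used for the entropies", {
  set.seed(11)
  qf <- quantize_intensities(matrix(runif(400), 20), M = 8)
  ec <- entropy_components(qf)
  mig_nats <- mean_information_gain(qf)$mig
  # recompute everything in bits
  mig_bits <- (ec$h_joint / log(2) - ec$h_marginal / log(2)) / log2(8^4 / 8)
  expect_equal(mig_nats, mig_bits, tolerance = 1e-12)
})

test_that("MIG increases with the iid-noise fraction of a mixed image", {
  mean_mig <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(q) {
    m <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      v <- matrix(0.5, 64, 64)
      mask <- matrix(runif(64 * 64) < q, 64, 64)
      v[mask] <- runif(sum(mask))
      mean_information_gain(quantize_intensities(v, M = 4))$mig
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(mean_mig) >= 0))
  expect_lt(mean_mig[1], 0.05)
  expect_gt(mean_mig[5], 0.9)
})

test_that("identical image bytes give identical results", {
  set.seed(5)
  v <- matrix(runif(64^2), 64)
  r1 <- mean_information_gain(quantize_intensities(v, M = 16))
  r2 <- mean_information_gain(quantize_intensities(v, M = 16))
  expect_identical(r1, r2)
})

test_that("site summary averages the five views as defined", {
  set.seed(9)
  imgs <- lapply(setNames(1:5, c("N", "E", "S", "W", "TOP")),
                 function(i) matrix(runif(32^2), 32))
  s <- site_mig_summary(imgs, M = 4)
  expect_equal(s$mig_sides, mean(s$per_view[c("N", "E", "S", "W")]))
  expect_equal(s$mig_top, unname(s$per_view["TOP"]))
  expect_equal(s$mig_all, (4 * s$mig_sides + s$mig_top) / 5)
  expect_equal(s$mig_all, mean(s$per_view))

  # five identical images: all three indices equal the single-image MIG
  one <- matrix(runif(32^2), 32)
  same <- setNames(rep(list(one), 5), c("N", "E", "S", "W", "TOP"))
  s2 <- site_mig_summary(same, M = 4)
  expect_equal(s2$mig_all, s2$mig_top)
  expect_equal(s2$mig_sides, s2$mig_top)

  expect_error(site_mig_summary(imgs[c("N", "E", "S", "TOP")]), "missing view\\(s\\): W")
  expect_error(site_mig_summary(c(imgs, list(X = one))), "unexpected view")
})

test_that("manifest-driven MIG table reads images and flags missing files", {
  dir <- withr::local_tempdir()
  set.seed(3)
  rows <- list()
  for (v in c("N", "E", "S", "W", "TOP")) {
    img <- array(rep(matrix(runif(16^2), 16), 3), dim = c(16, 16, 3))
    p <- file.path(dir, paste0("s1_", v, ".png"))
    png::writePNG(img, p)
    rows[[v]] <- data.frame(site_id = "s1", view = v, path = p)
  }
  manifest <- do.call(rbind, rows)
  tab <- site_mig_table(manifest, M = 4)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mig_all, (4 * tab$mig_sides + tab$mig_top) / 5)

  manifest$path[manifest$view == "TOP"] <- file.path(dir, "gone.png")
  expect_error(site_mig_table(manifest, M = 4), "site s1, view TOP")
})
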