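test_that("pearson screen flags strong pairs and reports undefined columns", {
  set.seed(31)
  x <- rnorm(50)
  X <- data.frame(a = x, b = x, c = -x, d = rnorm(50), e = rep(1, 50))
  sc <- pearson_screen(X, threshold = 0.5)
  expect_true(any(sc$flagged$var1 == "a" & sc$flagged$var2 == "b" &
                    abs(sc$flagged$r - 1) < 1e-12))
  expect_true(any(abs(sc$flagged$r + 1) < 1e-12)) # a vs -a
  expect_equal(sc$undefined, "e")

  set.seed(32)
  Y <- data.frame(p = rnorm(1e4), q = rnorm(1e4))
  sc2 <- pearson_screen(Y)
  expect_lt(abs(sc2$r["p", "q"]), 0.05)
  expect_equal(nrow(sc2$flagged), 0L)
  expect_error(pearson_screen(X[1:2, ]), "at least 3")
})

test_that("VIF matches its closed form and the iterative filter drops collinear sets", {
  set.seed(41)
  n <- 400
  # near-orthogonal noise: VIF close to 1
  X <- data.frame(matrix(rnorm(n * 4), n))
  expect_true(all(abs(vif(X) - 1) < 0.1))
  expect_equal(vif_filter(X)$dropped, character(0))

  # two correlated predictors: VIF = 1/(1 - r^2) exactly, one dropped
  x1 <- rnorm(n); x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  X2 <- data.frame(x1 = x1, x2 = x2)
  r <- cor(x1, x2)
  v <- vif(X2)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  expect_gt(v[["x1"]], 5) # r ~ .9 implies VIF ~ 5.26
  vf <- vif_filter(X2, threshold = 2)
  expect_length(vf$retained, 1L)
  expect_length(vf$dropped, 1L)

  # duplicated column: infinite VIF, one copy dropped with a warning
  X3 <- data.frame(a = x1, b = x1, c = rnorm(n))
  expect_warning(vf3 <- vif_filter(X3), "perfect collinearity")
  expect_true("c" %in% vf3$retained)
  expect_length(vf3$retained, 2L)

  # protection redirects the drop to the unprotected member
  vfp <- vif_filter(X2, threshold = 2, protect = "x2")
  expect_equal(vfp$retained, "x2")
  expect_equal(vfp$dropped, "x1")
})

test_that("VIF filtering is invariant to row and column order", {
  set.seed(43)
  n <- 200
  z <- rnorm(n)
  X <- data.frame(a = z + rnorm(n, 0, 0.3), b = z + rnorm(n, 0, 0.3),
                  c = z + rnorm(n, 0, 0.3), d = rnorm(n))
  ref <- vif_filter(X)
  expect_equal(sort(vif_filter(X[sample(n), ])$retained), sort(ref$retained))
  expect_equal(sort(vif_filter(X[, sample(4)])$retained), sort(ref$retained))
})

test_that("transformation log-offsets activity and z-scores predictors", {
  d <- data.frame(act = c(0, 2, 10), p1 = c(1, 2, 3), p2 = c(5, 5, 8),
                  green_space_type = c("a", "b", "c"))
  out <- standardize_and_transform(d, activity_cols = "act",
                                   predictor_cols = c("p1", "p2"))
  expect_equal(out$act, log1p(c(0, 2, 10)))
  expect_equal(out$act[1], 0)
  expect_equal(mean(out$p1), 0, tolerance = 1e-8)
  expect_equal(sd(out$p2), 1, tolerance = 1e-8)
  expect_identical(out$green_space_type, d$green_space_type)
  d$flat <- 3
  expect_error(standardize_and_transform(d, predictor_cols = "flat"), "flat")
  d$neg <- c(-1, 0, 1)
  expect_error(standardize_and_transform(d, activity_cols = "neg"), "non-negative")
})

test_that("standardization leaves t-statistics of a linear fit unchanged", {
  set.seed(51)
  d <- data.frame(x = rnorm(80, 10, 3))
  d$y <- 2 + 0.5 * d$x + rnorm(80)
  t_raw <- summary(lm(y ~ x, d))$coefficients["x", "t value"]
  dz <- standardize_and_transform(d, predictor_cols = "x")
  t_std <- summary(lm(y ~ x, dz))$coefficients["x", "t value"]
  expect_equal(t_raw, t_std, tolerance = 1e-10)
})

test_that("the activity mixed model handles degenerate group structure", {
  set.seed(61)
  d <- data.frame(green_space_type = rep(letters[1:6], each = 10))
  d$y <- rnorm(60, 5, 1) # no group structure at all
  fit <- suppressWarnings(fit_activity_model(d, "y", character(0)))
  expect_equal(fit$coefficients$estimate[1], mean(d$y), tolerance = 0.05)
  expect_lt(fit$random_intercept_variance, 0.05)
  expect_equal(fit$pseudo_r2, 0) # intercept-only: no fixed-effect variance

  # exactly equal group means force the variance to (near) zero with a warning
  d2 <- data.frame(green_space_type = rep(letters[1:4], each = 8))
  d2$y <- rep(c(1, 2), 16)
  expect_warning(fit2 <- fit_activity_model(d2, "y", character(0)), "singular")
  expect_equal(fit2$random_intercept_variance, 0, tolerance = 1e-8)
  expect_error(fit_activity_model(data.frame(y = 1:5, green_space_type = "a"),
                                  "y", character(0)), "at least 2 groups")
})

test_that("the activity model recovers known coefficients", {
  set.seed(62)
  ok <- vapply(1:20, function(r) {
    n <- 180; g <- rep(paste0("t", 1:9), each = 20)
    b <- rnorm(9, 0, 0.25)[as.integer(factor(g))]
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), green_space_type = g)
    d$y <- 3 - 0.2 * d$x1 + 0.2 * d$x2 + b + rnorm(n, 0, 0.45)
    fit <- suppressWarnings(fit_activity_model(d, "y", c("x1", "x2")))
    co <- fit$coefficients
    all(abs(co$estimate[-1] - c(-0.2, 0.2)) < 3 * co$se[-1])
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("richness models estimate dispersion and correct SEs when overdispersed", {
  set.seed(71)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  d$y <- rpois(n, exp(1 + 0.3 * d$x))
  fit <- fit_richness_model(d, "y", "x")
  expect_equal(fit$family, "poisson")
  expect_equal(fit$dispersion, 1, tolerance = 0.1)

  # negative-binomial counts with variance ~ 3x mean trigger the correction
  set.seed(72)
  mu <- exp(1 + 0.3 * d$x)
  d$y <- rnbinom(n, mu = mu, size = mu / 2) # var = mu + 2 mu = 3 mu
  fit2 <- fit_richness_model(d, "y", "x")
  expect_equal(fit2$family, "quasipoisson")
  expect_gt(fit2$dispersion, 1.5)
  # the quasi-Poisson SE equals the Poisson SE times sqrt(phi), term-wise
  se_pois <- summary(fit2$poisson_fit)$coefficients[, 2]
  expect_equal(fit2$coefficients$se, unname(se_pois * sqrt(fit2$dispersion)),
               tolerance = 1e-10)
  expect_error(fit_richness_model(data.frame(y = c(0.5, 1), x = 1:2), "y", "x"),
               "integer")
})

test_that("stepwise selection reduces to a direct AIC comparison for one term", {
  set.seed(81)
  n <- 120
  d <- data.frame(x = rnorm(n), green_space_type = rep(letters[1:6], 20))
  d$y <- 0.4 * d$x + rnorm(n)
  sel <- suppressWarnings(stepwise_aic(d, "y", "x", type = "activity"))
  a1 <- AIC(lme4::lmer(y ~ x + (1 | green_space_type), d, REML = FALSE))
  a0 <- AIC(lme4::lmer(y ~ 1 + (1 | green_space_type), d, REML = FALSE))
  expect_equal(sel$selected, if (a1 < a0) "x" else character(0))
  expect_equal(sel$path$aic[1], a1)
})

test_that("stepwise selection agrees with MASS::stepAIC on a Poisson GLM", {
  set.seed(82)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- rpois(n, exp(0.5 + 0.4 * d$x1))
  sel <- stepwise_aic(d, "y", c("x1", "x2", "x3"), type = "richness")
  ref <- MASS::stepAIC(glm(y ~ x1 + x2 + x3, d, family = poisson()),
                       trace = 0, direction = "both")
  expect_setequal(sel$selected, attr(terms(ref), "term.labels"))
})

test_that("all-noise candidate sets mostly collapse to the intercept-only model", {
  picks <- vapply(1:11, function(r) {
    set.seed(900 + r)
    n <- 120
    d <- data.frame(matrix(rnorm(n * 4), n), green_space_type = rep(letters[1:6], 20))
    d$y <- rnorm(n)
    sel <- suppressWarnings(stepwise_aic(d, "y", paste0("X", 1:4), type = "activity"))
    length(sel$selected) == 0L
  }, logical(1))
  expect_gt(mean(picks), 0.5)
})

test_that("pseudo-R2 behaves at its limits and grows with a true predictor", {
  set.seed(91)
  n <- 200
  d <- data.frame(x = rnorm(n), green_space_type = rep(letters[1:5], 40))
  d$y <- 1 + 0.8 * d$x # noise-free
  fit <- suppressWarnings(fit_activity_model(d, "y", "x"))
  expect_gt(fit$pseudo_r2, 0.99)

  d$y2 <- rpois(n, exp(0.5 + 0.5 * d$x))
  null_fit <- fit_richness_model(d, "y2", character(0))
  expect_equal(null_fit$pseudo_r2, 0)
  with_x <- fit_richness_model(d, "y2", "x")
  expect_gt(with_x$pseudo_r2, null_fit$pseudo_r2)
  expect_error(pseudo_r2(structure(list(), class = "lm")), "greenmig_fit")
})
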