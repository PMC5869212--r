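#' Configuration of the synthetic urban green-space study
#'
#' Bundles every parameter of the synthetic-data generator: the stratified
#' sampling design (9 green-space types x 4 size classes x 5 sites, 3 survey
#' nights), per-type latent habitat structure, scene-image rendering, and the
#' known effect structure driving the simulated bat surveys. Defaults
#' emulate the study conditions: 180 sites, 540 recording nights, total
#' log-activity declining with canopy complexity (standardized effect -0.2)
#' and increasing with ground cover (+0.2), a green-space-type random
#' intercept (sd 0.25), residual sd 0.45, and a 14-taxon occupancy ranking
#' running from 0.93 down to below 0.10. The open-space guild's share of
#' activity decays with canopy complexity faster than the edge-space guild's
#' (`delta_open`), so group-level responses differ in the expected
#' direction.
#'
#' @param seed Master seed; every generator output is a deterministic
#'   function of the configuration including this seed.
#' @param n_types,n_size_classes,n_per_cell,n_nights Design dimensions.
#' @param img_size Scene image edge length in pixels.
#' @param M_analysis Quantization bins used when the pipeline computes MIG on
#'   generated scenes (coarser than the 8-bit default because the synthetic
#'   scenes are small; see the package vignette).
#' @param beta0,beta_migtop,beta_ground Coefficients of the total-activity
#'   model on the log(activity + 1) scale; `beta_migtop` and `beta_ground`
#'   act on the z-scores of latent canopy complexity and ground cover.
#' @param tau,sigma Random-intercept and residual standard deviations.
#' @param delta_open,delta_other Log-share slopes on z(canopy complexity) for
#'   the open-space guild and ungrouped species, relative to edge-space.
#' @param occ_ground,occ_ctop Occupancy logit shifts per z-unit of ground
#'   cover and canopy complexity.
#' @param night_sd Log-normal sd of the night-to-night activity factors.
#' @param occupancy Named vector of 14 baseline occupancy probabilities.
#' @return A list of class `greenmig_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_types = 9L, n_size_classes = 4L, n_per_cell = 5L,
                             n_nights = 3L, img_size = 128L, M_analysis = 16L,
                             beta0 = 3.0, beta_migtop = -0.2, beta_ground = 0.2,
                             tau = 0.25, sigma = 0.45,
                             delta_open = -0.3, delta_other = -0.1,
                             occ_ground = 0.35, occ_ctop = -0.35,
                             night_sd = 0.25, occupancy = NULL) {
  if (tau < 0 || sigma < 0 || night_sd < 0) stop("standard deviations must be >= 0")
  if (is.null(occupancy)) {
    occupancy <- c(
      "P. pygmaeus" = 0.93, "P. kuhlii/P. nathusii" = 0.93, "N. noctula" = 0.88,
      "H. savii" = 0.73, "P. pipistrellus" = 0.61, "M. brandtii/M. mystacinus" = 0.33,
      "B. barbastellus" = 0.05, "M. alcathoe" = 0.04, "E. nilssonii" = 0.08,
      "Plecotus sp." = 0.06, "M. daubentonii" = 0.07, "M. myotis" = 0.03,
      "M. nattereri" = 0.04, "V. murinus" = 0.05)
  }
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy probabilities must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_types = n_types,
                 n_size_classes = n_size_classes, n_per_cell = n_per_cell,
                 n_nights = n_nights, img_size = as.integer(img_size),
                 M_analysis = as.integer(M_analysis),
                 beta0 = beta0, beta_migtop = beta_migtop, beta_ground = beta_ground,
                 tau = tau, sigma = sigma, delta_open = delta_open,
                 delta_other = delta_other, occ_ground = occ_ground,
                 occ_ctop = occ_ctop, night_sd = night_sd, occupancy = occupancy),
            class = "greenmig_config")
}

#' Tiny-profile configuration for fast end-to-end runs
#'
#' 12 sites (4 green-space types x 1 size class x 3 sites) with 64x64 scene
#' images; the whole pipeline runs in well under a minute on it.
#'
#' @inheritParams generator_config
#' @param ... Further overrides passed to [generator_config()].
#' @export
tiny_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_types = 4L, n_size_classes = 1L,
                   n_per_cell = 3L, img_size = 64L, ...)
}

# stage-specific deterministic sub-seed, kept inside 32-bit integer range
.sub_seed <- function(cfg, stage, i = 0L) {
  as.integer((as.numeric(cfg$seed) * 7919 + stage * 104729 + i) %% 2147483647)
}

# latent habitat means per green-space type: canopy complexity, side-view
# complexity, ground cover (%) -- forests dense and complex, pastures open
.type_latents <- data.frame(
  green_space_type = c("forest", "cemetery", "park", "street", "housing",
                       "health", "sports", "vineyard", "pasture"),
  c_top  = c(0.85, 0.60, 0.55, 0.50, 0.45, 0.40, 0.25, 0.20, 0.10),
  c_side = c(0.70, 0.45, 0.50, 0.30, 0.55, 0.35, 0.35, 0.60, 0.30),
  g      = c(55, 60, 70, 50, 60, 65, 70, 75, 80),
  stringsAsFactors = FALSE
)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate the stratified site design
#'
#' Draws the full site table: `n_types x n_size_classes x n_per_cell` sites
#' (180 under defaults), each with its green-space type, size-class quartile
#' index, and latent habitat state — canopy complexity `c_top`, side-view
#' complexity `c_side` (both in `[0, 1]`) and ground cover `g` (%). Latents
#' are type-shifted (forests complex, pastures open) with site-level noise.
#'
#' @param cfg A [generator_config()].
#' @return Data frame with columns `site_id`, `green_space_type`,
#'   `size_class`, `c_top`, `c_side`, `g`.
#' @export
generate_design <- function(cfg = generator_config()) {
  set.seed(.sub_seed(cfg, 1L))
  types <- .type_latents[seq_len(cfg$n_types), , drop = FALSE]
  grid <- expand.grid(rep = seq_len(cfg$n_per_cell),
                      size_class = seq_len(cfg$n_size_classes),
                      green_space_type = types$green_space_type,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  lat <- types[match(grid$green_space_type, types$green_space_type), ]
  data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    green_space_type = grid$green_space_type,
    size_class = grid$size_class,
    c_top = .clamp(lat$c_top + stats::rnorm(n, 0, 0.12), 0.02, 0.98),
    c_side = .clamp(lat$c_side + stats::rnorm(n, 0, 0.15), 0.02, 0.98),
    g = .clamp(lat$g + stats::rnorm(n, 0, 12), 2, 98),
    stringsAsFactors = FALSE
  )
}

# one grayscale scene: smooth low-frequency background with a Bernoulli(q)
# per-pixel admixture of iid uniform noise; realized MIG is monotone in q.
# The mixing fraction is q = 1 - (1-c)^(1/4) so that the fraction of 2x2
# windows containing noise -- the leading term of the joint entropy -- is
# linear in the latent complexity c, keeping realized MIG an approximately
# linear (not just monotone) proxy of the latent.
.mixing_fraction <- function(c) 1 - (1 - c)^(1 / 4)

.scene_matrix <- function(q, size) {
  xs <- seq(0, 1, length.out = size)
  fx <- stats::runif(1, 0.5, 1.5); fy <- stats::runif(1, 0.5, 1.5)
  px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
  bg <- 0.5 + 0.22 * outer(sin(2 * pi * fy * xs + py), sin(2 * pi * fx * xs + px)) +
    0.18 * outer(xs - 0.5, rep(1, size))
  bg <- .clamp(bg, 0, 1)
  mask <- matrix(stats::runif(size * size) < q, size, size)
  bg[mask] <- stats::runif(sum(mask))
  bg
}

#' Render the five scene images of one site
#'
#' Each view is a mixture of a smooth low-frequency background and iid pixel
#' noise, driven by the site's latent complexity (`c_side` for the four
#' cardinal side views, `c_top` for the upward canopy view). The per-pixel
#' noise probability is `1 - (1 - c)^(1/4)`, which makes the fraction of
#' 2x2 windows containing noise linear in the latent, so realized MIG is an
#' approximately linear — not merely monotone — proxy of it: a site with
#' latent 0 approaches the uniform-image limit (MIG near 0) and latent 1 the
#' random-image limit (MIG near 1).
#'
#' @param site One row of a [generate_design()] table (needs `c_top`,
#'   `c_side`, `site_id`).
#' @param cfg A [generator_config()].
#' @param site_index Integer used to derive the per-site RNG stream.
#' @return Named list of five intensity matrices (`N`, `E`, `S`, `W`,
#'   `TOP`), values in `[0, 1]`.
#' @export
generate_scene_images <- function(site, cfg = generator_config(), site_index = 1L) {
  set.seed(.sub_seed(cfg, 2L, site_index))
  imgs <- lapply(.mixing_fraction(c(N = site$c_side, E = site$c_side,
                                    S = site$c_side, W = site$c_side,
                                    TOP = site$c_top)),
                 .scene_matrix, size = cfg$img_size)
  imgs
}

#' Generate a site's field-vegetation measurements
#'
#' Touch probabilities in the understorey classes (0-2 m) rise with the
#' side-view complexity latent and ground cover; mid-storey classes mix both
#' latents; the canopy classes (10-15 m, >15 m) follow canopy complexity, so
#' a fully complex canopy yields near-saturated canopy clutter. Per-position
#' cover and height estimates and the plot tree list (counts rising with
#' canopy complexity, log-normal DBH) carry site-level observation noise, so
#' realized field descriptors correlate with — but do not duplicate — the
#' image-derived complexity of the same site.
#'
#' @inheritParams generate_scene_images
#' @return List with `touches` (17 x 10 binary matrix), `ground_cover`,
#'   `canopy_cover`, `veg_height` (length-17 vectors), and `dbh` (tree DBH
#'   vector in metres).
#' @export
generate_vegetation_profiles <- function(site, cfg = generator_config(), site_index = 1L) {
  set.seed(.sub_seed(cfg, 3L, site_index))
  cs <- site$c_side; ct <- site$c_top; g01 <- site$g / 100
  under <- cs * c(1.00, 0.90, 0.80, 0.70) + 0.15 * g01
  mid <- (0.75 * cs + 0.25 * ct) * c(0.65, 0.60, 0.55, 0.50)
  canopy <- ct * c(0.95, 0.85)
  p <- .clamp(c(under, mid, canopy) + 0.002, 0.002, 0.98)
  # per-class patchiness so descriptors are noisier than the latent itself
  p <- .clamp(p * exp(stats::rnorm(10, 0, 0.25)), 0.002, 0.98)
  touches <- matrix(stats::rbinom(17L * 10L, 1L, rep(p, each = 17L)), 17L, 10L)
  obs <- exp(stats::rnorm(3, 0, c(0.10, 0.22, 0.22))) # per-site observer factors
  ground_cover <- .clamp(site$g * obs[1] + stats::rnorm(17, 0, 8), 0, 100)
  canopy_cover <- .clamp(100 * ct * obs[2] + stats::rnorm(17, 0, 10), 0, 100)
  veg_height <- .clamp((2 + 26 * ct) * obs[3] + stats::rnorm(17, 0, 2), 0.1, 40)
  n_trees <- stats::rpois(1, 1 + 13 * .clamp(ct * exp(stats::rnorm(1, 0, 0.3)), 0, 1.5))
  dbh <- if (n_trees > 0) stats::rlnorm(n_trees, log(0.25), 0.35) else numeric(0)
  list(touches = touches, ground_cover = ground_cover, canopy_cover = canopy_cover,
       veg_height = veg_height, dbh = dbh)
}

.group_of <- function(species, cfg_sp) {
  ifelse(species %in% cfg_sp$functional_groups$edge_space, "edge",
         ifelse(species %in% cfg_sp$functional_groups$open_space, "open", "other"))
}

#' Simulate the acoustic bat surveys
#'
#' Per site, total activity follows the Gaussian mixed structure
#' `log(A + 1) = beta0 + beta_migtop * z(c_top) + beta_ground * z(g) +
#' b_type + eps` with `b_type ~ N(0, tau^2)` and `eps ~ N(0, sigma^2)`.
#' Species presence is drawn from occupancy probabilities whose logits shift
#' with ground cover (up) and canopy complexity (down). Activity is shared
#' among the species present with open-space foragers' share decaying in
#' canopy complexity faster than edge-space foragers' share, then spread
#' over the three survey nights with log-normal nightly factors and split
#' into individual call-sequence records.
#'
#' @param design A [generate_design()] table.
#' @param cfg A [generator_config()].
#' @param cfg_sp A [species_config()].
#' @return List with `records` (data frame `site_id`, `night_index`,
#'   `species_label`, `sequence_length_s`) and `nights` (the survey ledger:
#'   one row per surveyed site-night, including silent ones).
#' @export
generate_bat_surveys <- function(design, cfg = generator_config(),
                                 cfg_sp = species_config()) {
  set.seed(.sub_seed(cfg, 4L))
  z1 <- as.numeric(scale(design$c_top))
  z2 <- as.numeric(scale(design$g))
  types <- unique(design$green_space_type)
  b <- stats::setNames(stats::rnorm(length(types), 0, cfg$tau), types)
  occ <- cfg$occupancy
  grp <- .group_of(names(occ), cfg_sp)
  delta <- c(edge = 0, open = cfg$delta_open, other = cfg$delta_other)[grp]
  r_site <- character(0); r_night <- integer(0); r_sp <- character(0); r_len <- numeric(0)
  for (i in seq_len(nrow(design))) {
    eta <- cfg$beta0 + cfg$beta_migtop * z1[i] + cfg$beta_ground * z2[i] +
      b[[design$green_space_type[i]]] + stats::rnorm(1, 0, cfg$sigma)
    A <- max(exp(eta) - 1, 0)
    p_occ <- stats::plogis(stats::qlogis(.clamp(occ, 0.001, 0.999)) +
                             cfg$occ_ground * z2[i] + cfg$occ_ctop * z1[i])
    present <- stats::rbinom(length(occ), 1L, p_occ) == 1L
    u <- occ * exp(delta * z1[i]) * present
    if (A < 0.5 || sum(u) == 0) next
    share <- u / sum(u)
    f_night <- exp(stats::rnorm(cfg$n_nights, 0, cfg$night_sd))
    for (n in seq_len(cfg$n_nights)) {
      for (s in names(occ)[present]) {
        tot <- A * f_night[n] * share[[s]]
        if (tot < 0.05) next
        m <- 1L + stats::rpois(1, 1)
        lens <- tot * diff(c(0, sort(stats::runif(m - 1L)), 1))
        lens <- lens[lens > 0]
        r_site <- c(r_site, rep(design$site_id[i], length(lens)))
        r_night <- c(r_night, rep(n, length(lens)))
        r_sp <- c(r_sp, rep(s, length(lens)))
        r_len <- c(r_len, lens)
      }
    }
  }
  records <- data.frame(site_id = r_site, night_index = r_night,
                        species_label = r_sp, sequence_length_s = r_len,
                        stringsAsFactors = FALSE)
  nights <- expand.grid(site_id = design$site_id, night_index = seq_len(cfg$n_nights),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nights <- nights[order(nights$site_id, nights$night_index), ]
  rownames(nights) <- NULL
  list(records = records, nights = nights)
}

#' Run the whole synthetic study in memory
#'
#' Generates the design, renders every site's five scene images and computes
#' their MIG summaries (at `cfg$M_analysis` bins), builds the
#' field-vegetation descriptor table, and simulates the acoustic surveys and
#' their per-site response summaries.
#'
#' @param cfg A [generator_config()].
#' @param cfg_sp A [species_config()].
#' @return List of data frames: `design`, `mig`, `veg`, `responses`, plus
#'   `records` and `nights` from [generate_bat_surveys()].
#' @export
simulate_study <- function(cfg = generator_config(), cfg_sp = species_config()) {
  design <- generate_design(cfg)
  mig <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    imgs <- generate_scene_images(design[i, ], cfg, site_index = i)
    s <- site_mig_summary(imgs, M = cfg$M_analysis)
    data.frame(site_id = design$site_id[i], mig_all = s$mig_all,
               mig_sides = s$mig_sides, mig_top = s$mig_top,
               M = s$M, k = s$k, stringsAsFactors = FALSE)
  }))
  veg <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    pr <- generate_vegetation_profiles(design[i, ], cfg, site_index = i)
    d <- summarize_plot(pr$touches, pr$ground_cover, pr$canopy_cover,
                        pr$veg_height, pr$dbh)
    cl <- as.list(d$clutter)
    names(cl) <- paste0("clutter_", gsub("[ >]", "", gsub("-", "_", height_classes())))
    data.frame(site_id = design$site_id[i], cl,
               vertical_heterogeneity = d$vertical_heterogeneity,
               ground_cover = d$ground_cover, canopy_cover = d$canopy_cover,
               vegetation_height = d$vegetation_height,
               tree_density = d$tree_density, n_large_trees = d$n_large_trees,
               mean_dbh = d$mean_dbh, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  surveys <- generate_bat_surveys(design, cfg, cfg_sp)
  responses <- site_response_table(surveys$records, site_ids = design$site_id,
                                   cfg = cfg_sp)
  list(design = design, mig = mig, veg = veg, responses = responses,
       records = surveys$records, nights = surveys$nights)
}

#' Write a complete on-disk fixture bundle
#'
#' Materializes a synthetic study as the same file formats the real-data
#' loaders consume: an image manifest plus one PNG per view, the raw
#' vegetation CSVs (touches, per-position estimates, trees) and the acoustic
#' survey CSV. Everything is reproducible from the configuration seed.
#'
#' @param cfg A [generator_config()] (use [tiny_config()] for a fast 12-site
#'   bundle with 64x64 images).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixture_bundle <- function(cfg = generator_config(), dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, mode = 2) != 0) stop("output directory is not writable: ", dir)
  design <- generate_design(cfg)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  hc <- height_classes()
  manifest <- list(); touch <- list(); pos <- list(); trees <- list()
  for (i in seq_len(nrow(design))) {
    s <- design$site_id[i]
    imgs <- generate_scene_images(design[i, ], cfg, site_index = i)
    for (v in names(imgs)) {
      p <- file.path("images", sprintf("%s_%s.png", s, v))
      rgb <- array(rep(imgs[[v]], 3L), dim = c(dim(imgs[[v]]), 3L))
      png::writePNG(rgb, file.path(dir, p))
      manifest[[length(manifest) + 1L]] <- data.frame(
        site_id = s, view = v, path = p, stringsAsFactors = FALSE)
    }
    pr <- generate_vegetation_profiles(design[i, ], cfg, site_index = i)
    idx <- which(pr$touches == 1L, arr.ind = TRUE)
    if (nrow(idx)) {
      touch[[length(touch) + 1L]] <- data.frame(
        site_id = s, position_id = idx[, 1], height_class = hc[idx[, 2]],
        touch = 1L, stringsAsFactors = FALSE)
    }
    pos[[length(pos) + 1L]] <- data.frame(
      site_id = s, position_id = 1:17, ground_cover = pr$ground_cover,
      canopy_cover = pr$canopy_cover, veg_height = pr$veg_height,
      stringsAsFactors = FALSE)
    if (length(pr$dbh)) {
      trees[[length(trees) + 1L]] <- data.frame(site_id = s, dbh_m = pr$dbh,
                                                stringsAsFactors = FALSE)
    }
  }
  surveys <- generate_bat_surveys(design, cfg)
  paths <- list(
    design = file.path(dir, "design.csv"),
    manifest = file.path(dir, "manifest.csv"),
    touches = file.path(dir, "vegetation_touches.csv"),
    positions = file.path(dir, "vegetation_positions.csv"),
    trees = file.path(dir, "trees.csv"),
    surveys = file.path(dir, "surveys.csv"),
    nights = file.path(dir, "survey_nights.csv")
  )
  utils::write.csv(design, paths$design, row.names = FALSE)
  utils::write.csv(do.call(rbind, manifest), paths$manifest, row.names = FALSE)
  utils::write.csv(do.call(rbind, touch), paths$touches, row.names = FALSE)
  utils::write.csv(do.call(rbind, pos), paths$positions, row.names = FALSE)
  utils::write.csv(do.call(rbind, trees), paths$trees, row.names = FALSE)
  utils::write.csv(surveys$records, paths$surveys, row.names = FALSE)
  utils::write.csv(surveys$nights, paths$nights, row.names = FALSE)
  invisible(paths)
}
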