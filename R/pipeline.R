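#' Correlation-based pruning of redundant predictors
#'
#' The screening step applied before VIF filtering: while any pair of
#' candidate predictors is correlated beyond the threshold, drop the
#' unprotected member involved in the most over-threshold pairs (ties broken
#' by the larger mean absolute correlation among its flagged pairs, then
#' alphabetically). Protected columns — the image-derived complexity terms
#' and the design's size class — are never dropped here: when a field
#' descriptor duplicates an MIG term, the cheaper, objective image measure
#' is the one retained, and residual collinearity among protected columns is
#' left to the VIF filter.
#'
#' @param X Numeric data frame of candidate predictors.
#' @param threshold Absolute Pearson correlation above which a pair is
#'   redundant (default 0.5).
#' @param protect Character vector of columns never dropped.
#' @return List with `retained`, `dropped`, and `pairs` (the flagged pairs
#'   considered, from [pearson_screen()]).
#' @export
prune_correlated <- function(X, threshold = 0.5, protect = character(0)) {
  X <- as.data.frame(X)
  screen <- pearson_screen(X, threshold = threshold)
  dropped <- character(0)
  repeat {
    r <- suppressWarnings(stats::cor(X))
    idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
    if (!nrow(idx)) break
    pairs <- data.frame(v1 = rownames(r)[idx[, 1]], v2 = colnames(r)[idx[, 2]],
                        r = abs(r[idx]), stringsAsFactors = FALSE)
    droppable <- setdiff(unique(c(pairs$v1, pairs$v2)), protect)
    if (!length(droppable)) break
    score <- vapply(droppable, function(v) {
      sel <- pairs$v1 == v | pairs$v2 == v
      c(sum(sel), mean(pairs$r[sel]))
    }, numeric(2))
    ord <- order(-score[1, ], -score[2, ], droppable)
    drop <- droppable[ord[1]]
    dropped <- c(dropped, drop)
    X <- X[names(X) != drop]
  }
  list(retained = names(X), dropped = dropped, pairs = screen$flagged)
}

#' Assemble the site-level design matrix
#'
#' Joins the MIG table, the vegetation descriptors, the response table and
#' the design (type and size class) on `site_id`. Sites without large trees
#' have no mean DBH; that descriptor is set to 0 there (zero large-tree
#' biomass) so the matrix has no missing values.
#'
#' @param mig Site MIG table (`site_id`, `mig_all`, `mig_sides`, `mig_top`).
#' @param veg Vegetation descriptor table from
#'   [vegetation_descriptor_table()].
#' @param responses Response table from [site_response_table()].
#' @param design Site table with `site_id`, `green_space_type`, `size_class`.
#' @param mig_mode `"sides_top"` (separate side and top complexity terms) or
#'   `"all"` (the five-view mean as one term).
#' @return List with `data` (the merged data frame), `predictors` (all
#'   candidate predictor columns), `mig_cols`, and `response_cols`.
#' @export
assemble_design_matrix <- function(mig, veg, responses, design,
                                   mig_mode = c("sides_top", "all")) {
  mig_mode <- match.arg(mig_mode)
  d <- merge(design[c("site_id", "green_space_type", "size_class")], mig, by = "site_id")
  d <- merge(d, veg, by = "site_id")
  d <- merge(d, responses, by = "site_id")
  d$mean_dbh[is.na(d$mean_dbh)] <- 0
  if (anyNA(d)) stop("design matrix has missing values after assembly")
  mig_cols <- if (mig_mode == "all") "mig_all" else c("mig_sides", "mig_top")
  field_cols <- c(grep("^clutter_", names(veg), value = TRUE),
                  "vertical_heterogeneity", "ground_cover", "canopy_cover",
                  "vegetation_height", "tree_density", "n_large_trees", "mean_dbh")
  response_cols <- grep("^(activity|richness)_", names(responses), value = TRUE)
  list(data = d, predictors = c(field_cols, mig_cols, "size_class"),
       mig_cols = mig_cols, response_cols = response_cols)
}

#' Run the full analysis over an assembled study
#'
#' The modelling stage shared by the file-based pipeline and the in-memory
#' simulations: log-transform activities, z-score predictors, screen and
#' prune collinear field descriptors (protecting the MIG terms and size
#' class), VIF-filter the survivors, then select a model per response by
#' bidirectional stepwise AIC — Gaussian mixed models with a
#' green-space-type random intercept for activity responses, Poisson (with
#' quasi-Poisson SE correction under overdispersion) for richness.
#'
#' @param study List with `mig`, `veg`, `responses`, `design` (as produced
#'   by [simulate_study()] or loaded from files).
#' @param responses_to_fit Response columns to model (default: all eight).
#' @param mig_mode Passed to [assemble_design_matrix()].
#' @param r_threshold,vif_threshold,phi_threshold Screening, collinearity
#'   and overdispersion thresholds.
#' @return List with `data` (model-ready), `candidates`, `screen`,
#'   `pruned`, `vif`, and `fits` (per response: the [stepwise_aic()] result).
#' @export
analyze_study <- function(study,
                          responses_to_fit = NULL,
                          mig_mode = "sides_top",
                          r_threshold = 0.5, vif_threshold = 2,
                          phi_threshold = 1.5) {
  asm <- assemble_design_matrix(study$mig, study$veg, study$responses,
                                study$design, mig_mode = mig_mode)
  d <- asm$data
  if (is.null(responses_to_fit)) responses_to_fit <- asm$response_cols
  activity_cols <- grep("^activity_", responses_to_fit, value = TRUE)
  # a constant column (e.g. a single size class in a reduced design) carries
  # no information and cannot be z-scored; drop it from the candidate set
  constant <- asm$predictors[vapply(asm$predictors,
                                    function(p) stats::sd(d[[p]]) == 0, logical(1))]
  asm$predictors <- setdiff(asm$predictors, constant)
  d <- standardize_and_transform(d, activity_cols = activity_cols,
                                 predictor_cols = asm$predictors)
  protect <- c(asm$mig_cols, "size_class")
  pruned <- prune_correlated(d[asm$predictors], threshold = r_threshold,
                             protect = protect)
  # small-study guard: a VIF is only defined with more sites than predictors,
  # so tighten the redundancy threshold until the candidate set is identifiable
  thr <- r_threshold
  max_p <- max(length(protect), nrow(d) %/% 2)
  while (length(pruned$retained) > max_p && thr > 0.05) {
    thr <- thr - 0.05
    pruned <- prune_correlated(d[asm$predictors], threshold = thr,
                               protect = protect)
  }
  if (length(pruned$retained) > max_p) {
    keep <- c(intersect(pruned$retained, protect),
              utils::head(sort(setdiff(pruned$retained, protect)),
                          max(0L, max_p - length(protect))))
    pruned$dropped <- c(pruned$dropped, setdiff(pruned$retained, keep))
    pruned$retained <- keep
  }
  vf <- vif_filter(d[pruned$retained], threshold = vif_threshold,
                   protect = protect)
  candidates <- vf$retained
  screen <- pearson_screen(d[asm$predictors], threshold = r_threshold)
  fits <- lapply(stats::setNames(responses_to_fit, responses_to_fit), function(resp) {
    type <- if (grepl("^activity_", resp)) "activity" else "richness"
    stepwise_aic(d, resp, candidates, type = type,
                 group = "green_space_type", phi_threshold = phi_threshold)
  })
  list(data = d, candidates = candidates, screen = screen, pruned = pruned,
       vif = vf, fits = fits)
}

#' End-to-end pipeline over on-disk inputs
#'
#' Loads an image manifest, raw vegetation CSVs and the acoustic survey CSV
#' (the formats written by [make_fixture_bundle()]), computes the site MIG
#' table and descriptors, reduces the surveys to responses, runs
#' [analyze_study()], and writes the outputs: per-response coefficient
#' tables and selection logs, the correlation report, the site tables, and a
#' run manifest recording package version and configuration.
#'
#' @param paths Named list/vector with elements `design`, `manifest`,
#'   `touches`, `positions`, `trees`, `surveys` (file paths).
#' @param out_dir Output directory.
#' @param M Quantization bins for MIG.
#' @param mig_mode,responses_to_fit,r_threshold,vif_threshold,phi_threshold
#'   Passed to [analyze_study()].
#' @return Invisibly, the [analyze_study()] result plus `mig`, `veg`,
#'   `responses`, `out_files`.
#' @export
run_pipeline <- function(paths, out_dir, M = 256L,
                         mig_mode = "sides_top", responses_to_fit = NULL,
                         r_threshold = 0.5, vif_threshold = 2,
                         phi_threshold = 1.5) {
  for (p in c("design", "manifest", "touches", "positions", "trees", "surveys")) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
      stop("input file for '", p, "' not found",
           if (!is.null(paths[[p]])) paste0(": ", paths[[p]]))
    }
  }
  design <- utils::read.csv(paths$design, stringsAsFactors = FALSE)
  mig <- site_mig_table(paths$manifest, M = M)
  veg <- vegetation_descriptor_table(
    utils::read.csv(paths$touches, stringsAsFactors = FALSE),
    utils::read.csv(paths$positions, stringsAsFactors = FALSE),
    utils::read.csv(paths$trees, stringsAsFactors = FALSE))
  records <- utils::read.csv(paths$surveys, stringsAsFactors = FALSE)
  records$species_label <- merge_acoustic_groups(records$species_label)
  responses <- site_response_table(records, site_ids = design$site_id)
  res <- analyze_study(list(mig = mig, veg = veg, responses = responses,
                            design = design),
                       responses_to_fit = responses_to_fit, mig_mode = mig_mode,
                       r_threshold = r_threshold, vif_threshold = vif_threshold,
                       phi_threshold = phi_threshold)
  res$mig <- mig; res$veg <- veg; res$responses <- responses
  res$out_files <- write_pipeline_outputs(res, out_dir, M = M, mig_mode = mig_mode)
  invisible(res)
}

#' Write pipeline outputs to disk
#'
#' @param res An [analyze_study()] result (optionally with `mig`, `veg`,
#'   `responses` tables attached).
#' @param out_dir Output directory (created if needed).
#' @param M,mig_mode Recorded in the run manifest.
#' @return Named character vector of files written.
#' @export
write_pipeline_outputs <- function(res, out_dir, M = NA, mig_mode = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (tab in c("mig", "veg", "responses")) {
    if (!is.null(res[[tab]])) {
      f <- file.path(out_dir, paste0(tab, ".csv"))
      utils::write.csv(res[[tab]], f, row.names = FALSE)
      files[tab] <- f
    }
  }
  coef_rows <- lapply(names(res$fits), function(resp) {
    fit <- res$fits[[resp]]$fit
    cbind(response = resp, family = fit$family, fit$coefficients,
          pseudo_r2 = fit$pseudo_r2, dispersion = fit$dispersion,
          random_intercept_variance = fit$random_intercept_variance)
  })
  files["coefficients"] <- file.path(out_dir, "coefficients.csv")
  utils::write.csv(do.call(rbind, coef_rows), files["coefficients"], row.names = FALSE)
  path_rows <- lapply(names(res$fits), function(resp) {
    cbind(response = resp, res$fits[[resp]]$path)
  })
  files["selection_log"] <- file.path(out_dir, "selection_log.csv")
  utils::write.csv(do.call(rbind, path_rows), files["selection_log"], row.names = FALSE)
  files["correlations"] <- file.path(out_dir, "correlation_report.csv")
  utils::write.csv(res$screen$flagged, files["correlations"], row.names = FALSE)
  manifest <- c(
    package = "greenmig",
    version = as.character(utils::packageVersion("greenmig")),
    r_version = as.character(getRversion()),
    M = as.character(M), mig_mode = as.character(mig_mode),
    candidates = paste(res$candidates, collapse = ";"))
  files["run_manifest"] <- file.path(out_dir, "run_manifest.txt")
  writeLines(paste(names(manifest), manifest, sep = ": "), files["run_manifest"])
  files
}
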