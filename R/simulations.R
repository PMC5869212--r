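#' Parameter recovery of the activity mixed model
#'
#' Repeatedly simulates the survey design and acoustic records under the
#' generator defaults, reduces the records to total activity, and fits the
#' generating Gaussian mixed model — `log(activity + 1)` on the z-scores of
#' latent canopy complexity and ground cover with a green-space-type random
#' intercept. A replicate succeeds when both estimated effects fall within 3
#' standard errors of the generating values.
#'
#' @param n_rep Number of replicates.
#' @param seed Seed from which per-replicate configurations are derived.
#' @param cfg_base Base [generator_config()]; only its seed varies across
#'   replicates.
#' @return List with `rate` (share of successful replicates) and `details`
#'   (per-replicate estimates, SEs and success flags).
#' @export
simulate_parameter_recovery <- function(n_rep = 100L, seed = 1L,
                                        cfg_base = generator_config()) {
  cfg_sp <- species_config()
  details <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cfg_base
    cfg$seed <- as.integer((as.numeric(seed) * 9973 + r) %% 2147483647)
    design <- generate_design(cfg)
    sv <- generate_bat_surveys(design, cfg, cfg_sp)
    resp <- site_response_table(sv$records, site_ids = design$site_id, cfg = cfg_sp)
    d <- merge(design, resp, by = "site_id")
    d$y <- log1p(d$activity_total)
    d$z_ctop <- as.numeric(scale(d$c_top))
    d$z_ground <- as.numeric(scale(d$g))
    fit <- suppressWarnings(
      fit_activity_model(d, "y", c("z_ctop", "z_ground"), group = "green_space_type"))
    co <- fit$coefficients
    est <- stats::setNames(co$estimate, co$term)
    se <- stats::setNames(co$se, co$term)
    ok_mig <- abs(est["z_ctop"] - cfg$beta_migtop) < 3 * se["z_ctop"]
    ok_ground <- abs(est["z_ground"] - cfg$beta_ground) < 3 * se["z_ground"]
    details[[r]] <- data.frame(
      rep = r, est_migtop = est[["z_ctop"]], se_migtop = se[["z_ctop"]],
      est_ground = est[["z_ground"]], se_ground = se[["z_ground"]],
      success = ok_mig && ok_ground)
  }
  details <- do.call(rbind, details)
  list(rate = mean(details$success), details = details)
}

#' Selection consistency of the stepwise-AIC search
#'
#' Simulates a design with one true predictor (standardized effect
#' `effect`) plus `n_noise` pure-noise predictors, under the mixed-model
#' error structure (random type intercept sd `tau`, residual sd 1), and
#' counts how often the bidirectional stepwise search retains the true
#' predictor in its selected model.
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param effect True standardized coefficient (default 0.5).
#' @param n_noise Number of noise predictors (default 4).
#' @param n Sites (default 180) spread over `n_groups` types (default 9).
#' @param tau Random-intercept sd (default 0.25).
#' @return List with `rate` and `retained` (logical vector per replicate).
#' @export
simulate_stepwise_retention <- function(n_rep = 100L, seed = 1L, effect = 0.5,
                                        n_noise = 4L, n = 180L, n_groups = 9L,
                                        tau = 0.25) {
  retained <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(as.integer((as.numeric(seed) * 7907 + r) %% 2147483647))
    g <- rep(paste0("type", seq_len(n_groups)), length.out = n)
    b <- stats::setNames(stats::rnorm(n_groups, 0, tau), unique(g))
    X <- matrix(stats::rnorm(n * (n_noise + 1L)), n)
    colnames(X) <- c("x_true", paste0("noise", seq_len(n_noise)))
    d <- data.frame(X, green_space_type = g)
    d$y <- effect * d$x_true + b[g] + stats::rnorm(n)
    sel <- suppressWarnings(
      stepwise_aic(d, "y", colnames(X), type = "activity"))
    retained[r] <- "x_true" %in% sel$selected
  }
  list(rate = mean(retained), retained = retained)
}

#' End-to-end sign-structure recovery
#'
#' The full-study check: each replicate simulates the complete synthetic
#' study (scene images through acoustic surveys), runs the analysis pipeline
#' (screening, pruning, VIF, stepwise AIC), and records whether the
#' qualitative structure the generator encodes is recovered:
#' * the selected total-activity model retains the canopy-complexity term
#'   (`mig_top`) with a negative coefficient and ground cover with a
#'   positive coefficient;
#' * the canopy-complexity coefficient is more negative for open-space
#'   foragers than for edge-space foragers (full models on the candidate
#'   set, so the comparison is like-for-like).
#'
#' @param n_rep Number of replicates.
#' @param seed Base seed.
#' @param cfg_base Base [generator_config()]; only its seed varies.
#' @return List with `rate` (share of replicates recovering the full
#'   pattern) and `details` per replicate.
#' @export
simulate_sign_structure <- function(n_rep = 100L, seed = 1L,
                                    cfg_base = generator_config()) {
  details <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- cfg_base
    cfg$seed <- as.integer((as.numeric(seed) * 9929 + r) %% 2147483647)
    study <- simulate_study(cfg)
    res <- suppressWarnings(
      analyze_study(study, responses_to_fit = "activity_total"))
    co <- res$fits$activity_total$fit$coefficients
    est <- stats::setNames(co$estimate, co$term)
    ok_mig <- "mig_top" %in% co$term && est[["mig_top"]] < 0
    ok_ground <- "ground_cover" %in% co$term && est[["ground_cover"]] > 0
    d_grp <- res$data
    d_grp$activity_edge <- log1p(d_grp$activity_edge)
    d_grp$activity_open <- log1p(d_grp$activity_open)
    grp_coef <- vapply(c("activity_edge", "activity_open"), function(resp) {
      cand <- union(res$candidates, "mig_top")
      fit <- suppressWarnings(
        fit_activity_model(d_grp, resp, cand, group = "green_space_type"))
      cc <- fit$coefficients
      cc$estimate[cc$term == "mig_top"]
    }, numeric(1))
    ok_groups <- grp_coef[["activity_open"]] < grp_coef[["activity_edge"]]
    details[[r]] <- data.frame(
      rep = r, mig_top_negative = ok_mig, ground_positive = ok_ground,
      open_more_negative = ok_groups,
      success = ok_mig && ok_ground && ok_groups)
  }
  details <- do.call(rbind, details)
  list(rate = mean(details$success), details = details)
}
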