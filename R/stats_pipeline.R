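#' Pairwise Pearson correlation screen
#'
#' Computes all pairwise Pearson correlations among candidate predictors and
#' flags pairs whose |r| exceeds the threshold. Zero-variance columns have
#' undefined correlations; these pairs are reported separately rather than
#' silently dropped.
#'
#' @param X Numeric matrix or data frame of candidate predictors (columns
#'   named).
#' @param threshold Absolute-correlation flag level (default 0.5).
#' @return A list with `r` (full correlation matrix), `flagged` (data frame
#'   `var1`, `var2`, `r` for |r| > threshold), and `undefined` (character
#'   vector of zero-variance columns).
#' @export
pearson_screen <- function(X, threshold = 0.5) {
  X <- as.data.frame(X)
  if (nrow(X) < 3L) stop("need at least 3 observations per pair")
  num <- vapply(X, is.numeric, logical(1))
  X <- X[num]
  sds <- vapply(X, stats::sd, numeric(1))
  undefined <- names(X)[sds == 0]
  r <- suppressWarnings(stats::cor(X, method = "pearson"))
  pairs <- which(upper.tri(r) & abs(r) > threshold & !is.na(r), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[pairs[, 1]],
                        var2 = colnames(r)[pairs[, 2]],
                        r = r[pairs], stringsAsFactors = FALSE)
  flagged <- flagged[order(-abs(flagged$r)), , drop = FALSE]
  rownames(flagged) <- NULL
  list(r = r, flagged = flagged, undefined = undefined)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the linear regression of
#' predictor `j` on all other predictors. A single predictor has VIF 1; a
#' perfectly collinear predictor has VIF `Inf`.
#'
#' @param X Numeric data frame or matrix with at least as many rows as
#'   columns plus one.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (nrow(X) <= p) stop("VIF needs more rows than columns")
  if (p == 1L) return(stats::setNames(1, names(X)))
  vapply(names(X), function(j) {
    fit <- stats::lm(stats::reformulate(names(X)[names(X) != j], response = j), data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF collinearity filter
#'
#' Repeatedly drops the predictor with the largest VIF while any VIF exceeds
#' the threshold, recomputing VIFs after each drop. Ties (within 1e-8) are
#' broken by dropping the alphabetically first of the tied names, so the
#' result is deterministic and invariant to row and column order. A
#' perfectly collinear pair (infinite VIFs) loses one member with a warning.
#'
#' Columns listed in `protect` are never dropped: when collinearity involves
#' a protected column, the largest-VIF unprotected column is removed
#' instead, and filtering stops (with a warning) if only protected columns
#' remain above the threshold. This lets a pipeline keep its focal
#' predictors — here the image-derived complexity terms, which otherwise
#' tend to be the most predictable member of their collinearity cluster and
#' would be removed first — while redundant descriptors are filtered out.
#'
#' @param X Numeric data frame of candidate predictors.
#' @param threshold VIF level above which predictors are dropped (default 2).
#' @param protect Character vector of columns never dropped (default none).
#' @return A list with `retained` (character), `dropped` (character, in drop
#'   order), and `trace` (list of named VIF vectors, one per iteration).
#' @export
vif_filter <- function(X, threshold = 2, protect = character(0)) {
  X <- as.data.frame(X)
  dropped <- character(0)
  trace <- list()
  repeat {
    v <- vif(X)
    trace[[length(trace) + 1L]] <- v
    if (all(is.finite(v)) && max(v) <= threshold) break
    vd <- v[setdiff(names(v), protect)]
    if (!length(vd) || (all(is.finite(vd)) && max(vd) <= threshold)) {
      warning("VIF above threshold only among protected columns; stopping")
      break
    }
    vmax <- max(vd)
    worst <- names(vd)[if (is.finite(vmax)) vd >= vmax - 1e-8 else !is.finite(vd)]
    drop <- sort(worst)[1L]
    if (!is.finite(vmax)) {
      warning("perfect collinearity: dropping ", drop)
    }
    dropped <- c(dropped, drop)
    X <- X[names(X) != drop]
    if (ncol(X) <= 1L) break
  }
  list(retained = names(X), dropped = dropped, trace = trace)
}

#' Transform responses and standardize predictors for modelling
#'
#' Activity responses are log-transformed as `log(activity + 1)`; the +1
#' offset accommodates silent sites with zero activity. Continuous predictors
#' are z-scored to mean 0, sd 1, so coefficient magnitudes are comparable
#' across predictors. Grouping/categorical columns pass through untouched.
#'
#' @param data Data frame of sites.
#' @param activity_cols Columns to log(x+1)-transform (must be >= 0).
#' @param predictor_cols Continuous columns to standardize.
#' @return The data frame with transformed columns; standardization
#'   attributes (`centers`, `scales`) attached.
#' @export
standardize_and_transform <- function(data, activity_cols = character(0),
                                      predictor_cols = character(0)) {
  for (a in activity_cols) {
    if (any(data[[a]] < 0)) stop("activity must be non-negative in column ", a)
    data[[a]] <- log1p(data[[a]])
  }
  centers <- scales <- stats::setNames(numeric(length(predictor_cols)), predictor_cols)
  for (p in predictor_cols) {
    s <- stats::sd(data[[p]])
    if (!is.finite(s) || s == 0) stop("predictor is constant and cannot be standardized: ", p)
    centers[p] <- mean(data[[p]])
    scales[p] <- s
    data[[p]] <- (data[[p]] - centers[p]) / s
  }
  attr(data, "centers") <- centers
  attr(data, "scales") <- scales
  data
}

.fit_result <- function(model, family, coefficients, aic, dispersion = NA_real_,
                        random_intercept_variance = NA_real_, pseudo_r2 = NA_real_,
                        null_model = NULL) {
  structure(list(model = model, family = family, coefficients = coefficients,
                 aic = aic, dispersion = dispersion,
                 random_intercept_variance = random_intercept_variance,
                 pseudo_r2 = pseudo_r2, null_model = null_model),
            class = "greenmig_fit")
}

#' @export
print.greenmig_fit <- function(x, ...) {
  cat("greenmig fit (", x$family, "), AIC = ", round(x$aic, 2), "\n", sep = "")
  co <- x$coefficients
  co[-1] <- lapply(co[-1], round, digits = 4)
  print(co)
  if (is.finite(x$random_intercept_variance)) {
    cat("random-intercept variance:", signif(x$random_intercept_variance, 4), "\n")
  }
  if (is.finite(x$dispersion)) cat("dispersion:", signif(x$dispersion, 4), "\n")
  cat("pseudo-R2:", signif(x$pseudo_r2, 3), "\n")
  invisible(x)
}

#' Gaussian mixed model for (log) bat activity
#'
#' Fits a linear mixed model with a random intercept per green-space type,
#' accounting for multiple sampling sites within each type. Degrees of
#' freedom and p-values use the Satterthwaite approximation. A singular fit
#' (group variance estimated at zero) is a valid outcome and is reported
#' with a warning, not an error.
#'
#' @param data Model-ready data frame (see [standardize_and_transform()]).
#' @param response Name of the (already log-transformed) response column.
#' @param predictors Character vector of fixed-effect columns (may be empty
#'   for an intercept-only model).
#' @param group Name of the grouping column (default `"green_space_type"`).
#' @param REML Use REML (default, for reported coefficients) or ML (for AIC
#'   comparison across fixed-effect structures).
#' @return A `greenmig_fit` with family `"gaussian-mixed"`. `aic` is on the
#'   scale of the requested likelihood (ML when `REML = FALSE`).
#' @export
fit_activity_model <- function(data, response, predictors,
                               group = "green_space_type", REML = TRUE) {
  if (length(unique(data[[group]])) < 2L) stop("need at least 2 groups for a random intercept")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs, " + (1 | `", group, "`)"))
  fit <- lmerTest::lmer(fml, data = data, REML = REML)
  if (lme4::isSingular(fit)) {
    warning("singular fit: random-intercept variance estimated at zero")
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], statistic = sm[, "t value"],
                      p_value = sm[, "Pr(>|t|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == group][1]
  res <- .fit_result(fit, "gaussian-mixed", coefs, aic = stats::AIC(fit),
                     random_intercept_variance = tau2)
  res$pseudo_r2 <- pseudo_r2(res)
  res
}

#' Poisson / quasi-Poisson model for species richness
#'
#' Fits a Poisson GLM with log link and estimates the dispersion
#' `phi = Pearson chi-squared / residual df`. When `phi` exceeds
#' `phi_threshold` the counts are overdispersed and standard errors are
#' corrected with a quasi-Poisson refit, which rescales every standard error
#' by `sqrt(phi)`; the reported family then becomes `"quasipoisson"`. AIC is
#' always the Poisson (ML) AIC, so model selection remains likelihood-based.
#'
#' @inheritParams fit_activity_model
#' @param phi_threshold Dispersion above which the quasi-Poisson correction
#'   is applied (default 1.5).
#' @return A `greenmig_fit` with family `"poisson"` or `"quasipoisson"`.
#' @export
fit_richness_model <- function(data, response, predictors, phi_threshold = 1.5) {
  y <- data[[response]]
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("richness response must be non-negative integer counts")
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
  fit <- stats::glm(fml, data = data, family = stats::poisson())
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      statistic = sm[, 3], p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  family <- "poisson"
  if (phi > phi_threshold) {
    # quasi-likelihood correction: SEs scaled by sqrt(phi) term-wise, tests
    # referred to a t distribution on the residual df
    family <- "quasipoisson"
    coefs$se <- coefs$se * sqrt(phi)
    coefs$statistic <- coefs$estimate / coefs$se
    coefs$p_value <- 2 * stats::pt(-abs(coefs$statistic), stats::df.residual(fit))
  }
  res <- .fit_result(fit, family, coefs, aic = stats::AIC(fit), dispersion = phi)
  res$poisson_fit <- fit
  res$pseudo_r2 <- pseudo_r2(res)
  res
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starting from the model containing every candidate predictor, repeatedly
#' evaluates all single-term deletions and additions and applies the move
#' that lowers AIC the most, stopping when no move improves it. All AIC
#' values within one run come from the same likelihood type (ML; mixed
#' models are fitted with `REML = FALSE` during the search and the selected
#' model is refitted by REML for reporting). A candidate fit that fails to
#' converge is skipped with a warning.
#'
#' @param data Model-ready data frame.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictors (typically the
#'   [vif_filter()] survivors).
#' @param type `"activity"` (Gaussian mixed model) or `"richness"` (Poisson
#'   GLM).
#' @param group Grouping column for activity models.
#' @param phi_threshold Passed to [fit_richness_model()] for the final fit.
#' @return A list with `fit` (the selected model as a `greenmig_fit`,
#'   REML/quasi-corrected as appropriate), `selected` (retained predictors)
#'   and `path` (data frame logging each step's action and AIC).
#' @export
stepwise_aic <- function(data, response, candidates,
                         type = c("activity", "richness"),
                         group = "green_space_type", phi_threshold = 1.5) {
  type <- match.arg(type)
  # lightweight ML fits during the search: AIC is all that is needed, so the
  # Satterthwaite machinery of the reporting fits is skipped here
  ml_aic <- function(preds) {
    rhs <- if (length(preds)) paste(preds, collapse = " + ") else "1"
    tryCatch({
      if (type == "activity") {
        fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs,
                                        " + (1 | `", group, "`)"))
        fit <- suppressMessages(lme4::lmer(fml, data = data, REML = FALSE))
        stats::AIC(fit)
      } else {
        fml <- stats::as.formula(paste0("`", response, "` ~ ", rhs))
        stats::AIC(stats::glm(fml, data = data, family = stats::poisson()))
      }
    }, error = function(e) {
      warning("candidate fit failed (", conditionMessage(e), "); move skipped")
      NA_real_
    })
  }
  current <- sort(candidates)
  aic_now <- suppressWarnings(ml_aic(current))
  if (is.na(aic_now)) stop("full candidate model failed to fit")
  path <- data.frame(step = 0L, action = "start", term = NA_character_,
                     aic = aic_now, stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    moves <- rbind(
      if (length(current)) data.frame(action = "drop", term = current, stringsAsFactors = FALSE),
      if (length(setdiff(candidates, current)))
        data.frame(action = "add", term = setdiff(candidates, current), stringsAsFactors = FALSE)
    )
    if (is.null(moves) || !nrow(moves)) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      preds <- if (moves$action[i] == "drop") setdiff(current, moves$term[i])
               else sort(c(current, moves$term[i]))
      ml_aic(preds)
    }, numeric(1))
    moves <- moves[!is.na(moves$aic), , drop = FALSE]
    if (!nrow(moves) || min(moves$aic) >= aic_now - 1e-8) break
    best <- moves[order(moves$aic, moves$term), , drop = FALSE][1L, ]
    current <- if (best$action == "drop") setdiff(current, best$term)
               else sort(c(current, best$term))
    aic_now <- best$aic
    path <- rbind(path, data.frame(step = step_i, action = best$action,
                                   term = best$term, aic = best$aic,
                                   stringsAsFactors = FALSE))
  }
  fit <- if (type == "activity") {
    fit_activity_model(data, response, current, group = group, REML = TRUE)
  } else {
    fit_richness_model(data, response, current, phi_threshold = phi_threshold)
  }
  list(fit = fit, selected = current, path = path)
}

#' Pseudo-R-squared of a fitted model
#'
#' For GLMs: `1 - residual deviance / null deviance`. For the Gaussian mixed
#' model: the marginal pseudo-R2, i.e. the variance of the fixed-effect
#' predictions divided by the sum of that variance, the random-intercept
#' variance and the residual variance — the share of total variation
#' attributable to the fixed effects.
#'
#' @param fit A `greenmig_fit`.
#' @return A value in `[0, 1]` (up to estimation noise).
#' @export
pseudo_r2 <- function(fit) {
  if (!inherits(fit, "greenmig_fit")) stop("fit must be a greenmig_fit")
  if (fit$family == "gaussian-mixed") {
    m <- fit$model
    var_fixed <- stats::var(stats::predict(m, re.form = NA))
    vc <- as.data.frame(lme4::VarCorr(m))
    tau2 <- sum(vc$vcov[vc$grp != "Residual"])
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    var_fixed / (var_fixed + tau2 + sigma2)
  } else {
    m <- if (!is.null(fit$poisson_fit)) fit$poisson_fit else fit$model
    if (is.null(m$null.deviance)) stop("null model missing: cannot compute deviance pseudo-R2")
    1 - m$deviance / m$null.deviance
  }
}
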