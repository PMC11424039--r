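#' Model-fit container
#'
#' Shared result container for the mixed-model and per-network linear
#' fits: a coefficient table (estimate, SE, 95% CI, p), AIC, number of
#' parameters, adjusted R^2 where defined, and any interaction tests.
#'
#' @param label short model descriptor.
#' @param formula model formula (as character).
#' @param coefficients data.frame: term, estimate, se, ci_lo, ci_hi, p.
#' @param aic AIC of the fit (ML for mixed models).
#' @param n_par number of estimated parameters.
#' @param adj_r2 adjusted R^2 (fixed-effect models only).
#' @param converged logical.
#' @param meta named list of extras (p-value method, tests, ...).
#' @return A `model_fit` object.
#' @export
model_fit <- function(label, formula, coefficients, aic, n_par,
                      adj_r2 = NA_real_, converged = TRUE, meta = list()) {
  structure(list(label = label, formula = formula,
                 coefficients = coefficients, aic = aic, n_par = n_par,
                 adj_r2 = adj_r2, converged = converged, meta = meta),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Model [", x$label, "]: ", x$formula, "\n", sep = "")
  cat("  AIC ", format(x$aic), ", parameters ", x$n_par,
      if (!is.na(x$adj_r2)) paste0(", adj R2 ", signif(x$adj_r2, 3)), "\n",
      sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

wald_table <- function(est, se, df = Inf) {
  tval <- est / se
  p <- 2 * pt(-abs(tval), df = df)
  ci <- qt(0.975, df = df) * se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - ci), ci_hi = unname(est + ci),
             p = unname(p), row.names = NULL)
}

lm_fit_table <- function(fit) {
  sm <- summary(fit)
  co <- sm$coefficients
  wald_table(setNames(co[, 1], rownames(co)), co[, 2], df = fit$df.residual)
}

#' Mixed-effects models of network measures on age
#'
#' Fits, for one network measure, a nested set of linear mixed models over
#' the per-(subject, network) metric table with a subject-level random
#' intercept:
#' 1. `age + sex + network + icv`
#' 2. `+ age:network`
#' 3. `+ age:sex`
#' 4. `age * network * sex + icv` (all two- and three-way interactions)
#' All models are fitted by maximum likelihood so AICs are comparable.
#' Each interaction model carries a likelihood-ratio test against the
#' base model (recorded in `meta$interaction_test`; `meta$p_method`
#' documents the p-value method). ICV is standardized internally.
#' Whole-brain rows are excluded.
#'
#' @param metric_table output of [compute_metric_table()] (needs columns
#'   subject, group, age, sex, icv and the metric).
#' @param metric name of the metric column to model.
#' @return list of `model_fit` objects, one per model in the set.
#' @export
fit_metric_lmm <- function(metric_table, metric = "mean_strength") {
  df <- metric_table[metric_table$group != "whole_brain", , drop = FALSE]
  df <- df[!is.na(df[[metric]]), , drop = FALSE]
  if (length(unique(df$group)) < 2 || length(unique(df$subject)) < 2) {
    stop_invalid("need >= 2 groups and >= 2 subjects")
  }
  df$y <- df[[metric]]
  df$icv_s <- as.numeric(scale(df$icv))
  df$network <- factor(df$group)
  df$sex <- factor(df$sex)
  forms <- c(
    main_effects      = "y ~ age + sex + network + icv_s + (1 | subject)",
    age_by_network    = "y ~ age + sex + network + icv_s + age:network + (1 | subject)",
    age_by_sex        = "y ~ age + sex + network + icv_s + age:sex + (1 | subject)",
    age_network_sex   = "y ~ age * network * sex + icv_s + (1 | subject)"
  )
  fits <- list()
  base_ll <- NULL
  for (nm in names(forms)) {
    lf <- tryCatch(
      suppressMessages(lme4::lmer(as.formula(forms[[nm]]), data = df,
                                  REML = FALSE)),
      error = function(e) NULL)
    if (is.null(lf)) {
      fits[[nm]] <- model_fit(nm, forms[[nm]],
                              data.frame(), NA_real_, NA_integer_,
                              converged = FALSE)
      warning("model ", nm, " failed to fit; excluded from selection")
      next
    }
    # a singular (boundary) random-effect fit is a valid converged fit;
    # only genuine optimizer convergence failures disqualify a model
    msgs <- lf@optinfo$conv$lme4$messages %||% character(0)
    conv <- length(msgs[!grepl("boundary \\(singular\\)", msgs)]) == 0
    est <- lme4::fixef(lf)
    se <- sqrt(diag(as.matrix(lme4::vcov.merMod(lf))))
    tab <- wald_table(est, se)
    npar <- attr(logLik(lf), "df")
    meta <- list(p_method = "wald-normal (coefficients); LRT (interaction terms)")
    if (nm == "main_effects") {
      base_ll <- logLik(lf)
    } else if (!is.null(base_ll)) {
      stat <- as.numeric(2 * (logLik(lf) - base_ll))
      dfd <- npar - attr(base_ll, "df")
      meta$interaction_test <- data.frame(
        comparison = paste(nm, "vs main_effects"),
        chisq = stat, df = dfd,
        p = pchisq(max(stat, 0), dfd, lower.tail = FALSE))
    }
    fits[[nm]] <- model_fit(nm, forms[[nm]], tab, AIC(lf), npar,
                            converged = conv, meta = meta)
  }
  fits
}

#' AIC model selection
#'
#' Returns the converged fit with the lowest AIC; ties are broken toward
#' the model with fewer parameters.
#'
#' @param fits list of `model_fit` objects (e.g. from [fit_metric_lmm()]).
#' @return the selected `model_fit`.
#' @export
select_model <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic),
               logical(1))
  if (!any(ok)) stop("all model fits failed; nothing to select")
  cand <- fits[ok]
  aics <- vapply(cand, `[[`, numeric(1), "aic")
  npars <- vapply(cand, `[[`, numeric(1), "n_par")
  best <- which(aics == min(aics))
  if (length(best) > 1) best <- best[which.min(npars[best])]
  cand[[best]]
}

#' Per-network linear model of a measure on age
#'
#' Ordinary least squares of the metric on age + sex + ICV within one
#' network's rows; reports the adjusted R^2, the age coefficient's p, and
#' a significance flag at `alpha` (default 0.005).
#'
#' @param metric_table output of [compute_metric_table()].
#' @param group network name.
#' @param metric metric column name.
#' @param alpha significance threshold (default 0.005).
#' @param extra_covariates optional extra covariate column names (e.g.
#'   `"density"`); zero-variance covariates are dropped with a warning.
#' @return a `model_fit` with `meta$age_p` and `meta$significant`.
#' @export
per_network_glm <- function(metric_table, group, metric = "mean_strength",
                            alpha = 0.005, extra_covariates = character(0)) {
  df <- metric_table[metric_table$group == group, , drop = FALSE]
  df <- df[!is.na(df[[metric]]), , drop = FALSE]
  if (nrow(df) == 0) stop_invalid("no rows for group ", group)
  df$y <- df[[metric]]
  df$icv_s <- as.numeric(scale(df$icv))
  covs <- c("age", "sex", "icv_s")
  for (v in extra_covariates) {
    if (var(df[[v]], na.rm = TRUE) == 0) {
      warning("covariate ", v, " has zero variance; dropped")
    } else {
      covs <- c(covs, v)
    }
  }
  form <- paste("y ~", paste(covs, collapse = " + "))
  if (nrow(df) <= length(covs) + 1) stop("fewer rows than parameters in group ", group)
  fit <- lm(as.formula(form), data = df)
  tab <- lm_fit_table(fit)
  age_p <- tab$p[tab$term == "age"]
  model_fit(paste0("glm_", group), form, tab, AIC(fit),
            length(coef(fit)) + 1L,
            adj_r2 = summary(fit)$adj.r.squared,
            meta = list(group = group, metric = metric, alpha = alpha,
                        age_estimate = tab$estimate[tab$term == "age"],
                        age_p = age_p,
                        significant = is.finite(age_p) && age_p < alpha))
}

#' Sex main effect and age-by-sex interaction within a network
#'
#' Fits `metric ~ age * sex + icv` within the group and returns the sex
#' main-effect and age:sex coefficient rows (estimate, 95% CI, p). The
#' male level is the reported contrast (positive = M > F).
#'
#' @inheritParams per_network_glm
#' @return data.frame of the two coefficient rows.
#' @export
sex_contrasts <- function(metric_table, group, metric = "mean_strength") {
  df <- metric_table[metric_table$group == group, , drop = FALSE]
  df <- df[!is.na(df[[metric]]), , drop = FALSE]
  if (length(unique(df$sex)) < 2) stop("group ", group, " has a single sex")
  df$y <- df[[metric]]
  df$icv_s <- as.numeric(scale(df$icv))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  fit <- lm(y ~ age * sex + icv_s, data = df)
  tab <- lm_fit_table(fit)
  out <- tab[tab$term %in% c("sexM", "age:sexM"), , drop = FALSE]
  out$term <- c("sex (M - F)", "age x sex (M - F slope)")[
    match(out$term, c("sexM", "age:sexM"))]
  rownames(out) <- NULL
  out
}

#' Replicate per-network models with connection density as covariate
#'
#' Re-runs [per_network_glm()] for every network with `density` added to
#' the covariates and reports which significance flags change.
#'
#' @inheritParams per_network_glm
#' @return list with `fits` (per-group `model_fit`s) and `flags`
#'   (data.frame: group, significant, significant_density_adjusted,
#'   changed).
#' @export
density_adjusted_replication <- function(metric_table,
                                         metric = "mean_strength",
                                         alpha = 0.005) {
  if (!"density" %in% names(metric_table)) {
    stop_invalid("metric table has no density column")
  }
  groups <- setdiff(unique(metric_table$group), "whole_brain")
  fits <- list()
  flags <- NULL
  for (g in groups) {
    f0 <- per_network_glm(metric_table, g, metric, alpha)
    f1 <- per_network_glm(metric_table, g, metric, alpha,
                          extra_covariates = "density")
    fits[[g]] <- f1
    flags <- rbind(flags, data.frame(
      group = g,
      significant = f0$meta$significant,
      significant_density_adjusted = f1$meta$significant,
      changed = f0$meta$significant != f1$meta$significant))
  }
  list(fits = fits, flags = flags)
}

#' Write model fits as a CSV
#'
#' One row per coefficient of each fit, with the fit's label, AIC and
#' adjusted R^2 repeated.
#'
#' @param fits list of `model_fit` objects.
#' @param path CSV path.
#' @export
write_model_fits <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    if (nrow(f$coefficients) == 0) return(NULL)
    cbind(model = f$label, f$coefficients, aic = f$aic, adj_r2 = f$adj_r2)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
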