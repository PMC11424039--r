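#' Elastic-net feature importance for age prediction
#'
#' The feature-importance protocol for local network efficiency: split
#' subjects 80:20 into training and validation sets (stratified by age
#' tertile by default, so small validation sets stay representative;
#' `stratify = FALSE` gives a plain random split), z-scale the features
#' with training-set statistics only, and fit elastic-net regressions
#' minimizing
#' `(1/2n) ||y - b0 - X b||^2 + lambda * (rho ||b||_1 + (1-rho)/2 ||b||_2^2)`
#' over the printed L1-ratio grid and a logarithmic lambda grid, choosing
#' the pair with the best mean k-fold cross-validated R^2 on the training
#' set. The chosen model is refitted on the full training set and
#' evaluated on the validation set; features are ranked by absolute
#' coefficient.
#'
#' @param node_features numeric matrix, subjects x nodes (e.g. from
#'   [node_local_efficiency()]).
#' @param ages numeric response (years), one per subject.
#' @param split training fraction (default 0.8).
#' @param l1_grid L1-ratio (rho) grid; default
#'   `c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1)`.
#' @param k_folds cross-validation folds (default 5).
#' @param seed integer seed (split and fold assignment).
#' @param stratify stratify the split by age tertile (default TRUE).
#' @param n_lambda number of lambda values (log-spaced over
#'   `[1e-4, 10] * max|X'y|/n` on the scaled training data).
#' @return A `feature_importance` object: `weights` (named coefficients),
#'   `l1_ratio`, `lambda`, `r2_validation`, `rmse_validation`, `ranking`
#'   (data.frame node, weight, rank, cum_share), `cv` (grid search table),
#'   `dropped` (constant features), and split metadata.
#' @export
elasticnet_feature_importance <- function(node_features, ages, split = 0.8,
                                          l1_grid = c(0.1, 0.5, 0.7, 0.9,
                                                      0.95, 0.99, 1),
                                          k_folds = 5, seed = 1,
                                          stratify = TRUE, n_lambda = 50) {
  X <- as.matrix(node_features)
  y <- as.numeric(ages)
  n <- nrow(X)
  if (n < 10) stop_invalid("need at least 10 subjects")
  if (length(y) != n) stop_invalid("ages must match the feature rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  with_seed(seed, {
    idx_train <- if (stratify) {
      tert <- cut(y, quantile(y, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                  labels = FALSE)
      sort(unlist(lapply(split(seq_len(n), tert), function(ii) {
        sample(ii, round(split * length(ii)))
      }), use.names = FALSE))
    } else {
      sort(sample.int(n, round(split * n)))
    }
    idx_val <- setdiff(seq_len(n), idx_train)
    Xtr <- X[idx_train, , drop = FALSE]; ytr <- y[idx_train]
    Xva <- X[idx_val, , drop = FALSE];  yva <- y[idx_val]

    sds <- apply(Xtr, 2, sd)
    dropped <- colnames(Xtr)[sds == 0]
    if (length(dropped) > 0) {
      warning("constant feature(s) dropped: ", paste(dropped, collapse = ", "))
      Xtr <- Xtr[, sds > 0, drop = FALSE]
      Xva <- Xva[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    mus <- colMeans(Xtr)
    Ztr <- scale(Xtr, center = mus, scale = sds)
    Zva <- scale(Xva, center = mus, scale = sds)

    lam_max <- max(abs(crossprod(Ztr, ytr - mean(ytr)))) / nrow(Ztr)
    lambdas <- lam_max * 10^seq(1, -4, length.out = n_lambda)

    folds <- sample(rep_len(seq_len(k_folds), nrow(Ztr)))
    cv <- expand.grid(l1_ratio = l1_grid, lambda = lambdas)
    cv$r2 <- NA_real_
    r2sum <- matrix(0, length(l1_grid), n_lambda)
    for (f in seq_len(k_folds)) {
      hold <- folds == f
      for (a in seq_along(l1_grid)) {
        fit <- enet_exact(Ztr[!hold, , drop = FALSE], ytr[!hold],
                          l1_grid[a], lambdas)
        pred <- enet_predict(fit, Ztr[hold, , drop = FALSE])
        sst <- sum((ytr[hold] - mean(ytr[hold]))^2)
        r2sum[a, ] <- r2sum[a, ] +
          (1 - colSums((ytr[hold] - pred)^2) / sst) / k_folds
      }
    }
    for (a in seq_along(l1_grid)) {
      cv$r2[cv$l1_ratio == l1_grid[a]] <- r2sum[a, ]
    }
    best <- which.max(cv$r2)
    rho <- cv$l1_ratio[best]; lam <- cv$lambda[best]
    j <- match(lam, lambdas)

    fit <- enet_exact(Ztr, ytr, rho, lambdas, thresh = 1e-14)
    beta <- c(fit$a0[j], fit$beta[, j])
    names(beta) <- c("(Intercept)", colnames(Ztr))
    b0 <- beta[1]; w <- beta[-1]

    pred_va <- b0 + as.numeric(Zva %*% w)
    r2_val <- 1 - sum((yva - pred_va)^2) / sum((yva - mean(yva))^2)
    rmse_val <- sqrt(mean((yva - pred_va)^2))

    ord <- order(abs(w), decreasing = TRUE)
    tot <- sum(abs(w))
    ranking <- data.frame(
      node = names(w)[ord], weight = unname(w[ord]),
      rank = seq_along(w),
      cum_share = if (tot > 0) cumsum(abs(w[ord])) / tot else NA_real_)

    structure(list(
      weights = w, intercept = unname(b0), l1_ratio = rho, lambda = lam,
      r2_validation = r2_val, rmse_validation = rmse_val,
      ranking = ranking, cv = cv, dropped = dropped,
      idx_train = idx_train, idx_val = idx_val,
      scaling = list(center = mus, scale = sds),
      train = list(X = Ztr, y = ytr),
      meta = list(split = split, k_folds = k_folds, seed = seed,
                  stratify = stratify, n_lambda = n_lambda)
    ), class = "feature_importance")
  })
}

# Exact elastic-net path at the stated objective
#   (1/2n)||y - b0 - X b||^2 + lambda (rho ||b||_1 + (1-rho)/2 ||b||_2^2).
# glmnet standardizes the response by its population SD internally, which
# rescales the ridge part of the penalty relative to this objective; fitting
# y/s with alpha' = (rho/s) / (rho/s + 1 - rho) and lambda' = lambda *
# (rho/s + 1 - rho), then back-transforming b = s * c, makes the returned
# coefficients exact minimizers of the objective above at (lambda, rho).
enet_exact <- function(Z, y, rho, lambdas, thresh = 1e-12) {
  n <- length(y)
  s <- sd(y) * sqrt((n - 1) / n)
  fac <- rho / s + 1 - rho
  fit <- glmnet::glmnet(Z, y / s, alpha = min(1, (rho / s) / fac),
                        lambda = lambdas * fac,
                        standardize = FALSE, thresh = thresh)
  list(a0 = s * as.numeric(fit$a0),
       beta = s * as.matrix(fit$beta))
}

enet_predict <- function(fit, Znew) {
  sweep(Znew %*% fit$beta, 2, fit$a0, "+")
}

#' @export
print.feature_importance <- function(x, ...) {
  cat("Elastic-net feature importance:", length(x$weights), "features\n")
  cat("  chosen L1 ratio", x$l1_ratio, "lambda", signif(x$lambda, 3), "\n")
  cat("  validation R2", signif(x$r2_validation, 3),
      "RMSE", signif(x$rmse_validation, 3), "\n")
  print(head(x$ranking, 5), digits = 3)
  invisible(x)
}

#' Cumulative absolute-weight share of the top-k features
#'
#' Sum of the k largest absolute coefficients divided by the sum of all
#' absolute coefficients; NA (with a warning) when every weight is zero.
#'
#' @param result a `feature_importance` object.
#' @param k number of top features.
#' @return fraction in \[0, 1\].
#' @export
cumulative_weight_share <- function(result, k) {
  w <- abs(result$weights)
  if (k > length(w)) stop_invalid("k exceeds the number of features")
  if (sum(w) == 0) {
    warning("all coefficients are zero; share undefined")
    return(NA_real_)
  }
  sum(sort(w, decreasing = TRUE)[seq_len(k)]) / sum(w)
}

#' Elastic-net KKT (subgradient) violation
#'
#' Maximum violation of the stationarity conditions of the elastic-net
#' objective at `(intercept, beta)`:
#' for nonzero coefficients `|(-1/n) X_j'r + lambda (1-rho) b_j +
#' lambda rho sign(b_j)|`, for zero coefficients
#' `max(0, |X_j'r|/n - lambda rho)`, plus the intercept condition
#' `|mean(r)|`. Independent of the solver, so it certifies optimality of
#' any returned solution.
#'
#' @param X design matrix (as used in the fit, i.e. scaled).
#' @param y response.
#' @param beta coefficient vector (no intercept).
#' @param intercept fitted intercept.
#' @param lambda,rho elastic-net penalty and L1 ratio.
#' @return scalar maximum violation.
#' @export
enet_kkt_violation <- function(X, y, beta, intercept, lambda, rho) {
  n <- nrow(X)
  r <- y - intercept - as.numeric(X %*% beta)
  g <- as.numeric(crossprod(X, r)) / n
  nz <- beta != 0
  v_nz <- if (any(nz)) {
    max(abs(-g[nz] + lambda * (1 - rho) * beta[nz] +
              lambda * rho * sign(beta[nz])))
  } else 0
  v_z <- if (any(!nz)) max(0, max(abs(g[!nz])) - lambda * rho) else 0
  max(v_nz, v_z, abs(mean(r)))
}

#' Write feature-importance ranking as CSV
#' @param result a `feature_importance` object.
#' @param path CSV path.
#' @export
write_feature_importance <- function(result, path) {
  write.csv(result$ranking, path, row.names = FALSE)
  invisible(path)
}
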