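#' Configuration of the two-phase model fit
#'
#' Phase one runs an L1-penalised logistic regression down a geometric
#' lambda grid with k-fold cross-validation, capping the active set at
#' `max_active_predictors`; phase two refits the selected variables by
#' plain maximum-likelihood logistic regression so the final coefficients
#' are free of shrinkage and interpretable as log-odds per code.
#'
#' @param nfolds number of cross-validation folds (default 4).
#' @param max_active_predictors cap on the number of selected variables
#'   (default 50).
#' @param nlambda number of grid points on the log-scale lambda path.
#' @param lambda_min_ratio smallest lambda as a fraction of the
#'   data-derived `lambda_max` (the smallest lambda with an empty model).
#' @param standardize standardise features inside the penalised phase only
#'   (the refit always runs on the raw 0/1 features).
#' @param rule how the path point is chosen among models within the active
#'   cap: `"cv_1se"` (default) takes the sparsest model whose mean CV
#'   deviance lies within one standard error of the best — the standard
#'   guard against the near-flat tail of the CV curve, where the literal
#'   argmin is decided by noise and drags in spurious predictors;
#'   `"cv_min"` takes the literal deviance minimiser.
#' @param seed integer seed controlling the fold assignment.
#' @return list of class `lasso_config`.
#' @export
lasso_config <- function(nfolds = 4L, max_active_predictors = 50L,
                         nlambda = 100L, lambda_min_ratio = 1e-4,
                         standardize = TRUE, rule = c("cv_1se", "cv_min"),
                         seed = 1L) {
  stopifnot(nfolds >= 2L, max_active_predictors >= 1L, nlambda >= 2L,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(nfolds = as.integer(nfolds),
                 max_active_predictors = as.integer(max_active_predictors),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = isTRUE(standardize),
                 rule = match.arg(rule),
                 seed = as.integer(seed)),
            class = "lasso_config")
}

#' Phase one: cross-validated Lasso feature selection
#'
#' Fits the penalised logistic path with [glmnet::cv.glmnet()] (binomial
#' deviance loss), folds assigned by a seeded permutation, path traversal
#' stopped once the active set would exceed the cap. The chosen model is
#' the path point with the best mean cross-validated deviance among those
#' with at most `max_active_predictors` nonzero coefficients; the selected
#' features are its nonzero coefficients.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param config a [lasso_config()].
#' @return list with `selected` (feature names), `lambda` (chosen value),
#'   `path` (`data.table`: `lambda`, `n_active`, `cv_deviance`, `cv_sd`),
#'   and `foldid`.
#' @export
lasso_select <- function(fm, config = lasso_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "lasso_config"))
  y <- fm$label
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  x <- fm$matrix
  if (ncol(x) == 0L || nrow(x) == 0L) stop("empty feature matrix")

  set.seed(config$seed)
  n <- length(y)
  foldid <- sample(rep_len(seq_len(config$nfolds), n))

  # truncation of the path once the active set would exceed the cap is the
  # designed stop rule, not an anomaly worth surfacing
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(
      x, y, family = "binomial", type.measure = "deviance",
      foldid = foldid, nlambda = config$nlambda,
      lambda.min.ratio = config$lambda_min_ratio,
      pmax = config$max_active_predictors,
      standardize = config$standardize
    ),
    warning = function(w) {
      if (grepl("exceeds pmax", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  path <- data.table(lambda = cv$lambda, n_active = cv$nzero,
                     cv_deviance = cv$cvm, cv_sd = cv$cvsd)
  ok <- which(path$n_active <= config$max_active_predictors)
  best_min <- ok[which.min(path$cv_deviance[ok])]
  best <- if (config$rule == "cv_min") {
    best_min
  } else {
    cutoff <- path$cv_deviance[best_min] + path$cv_sd[best_min]
    ok[min(which(path$cv_deviance[ok] <= cutoff))]  # largest qualifying lambda
  }
  lam <- path$lambda[best]
  beta <- coef(cv, s = lam)[-1L, 1L]
  selected <- names(beta)[beta != 0]
  list(selected = selected, lambda = lam, path = path, foldid = foldid)
}

#' Phase two: unpenalised logistic refit
#'
#' Maximum-likelihood logistic regression of the labels on the selected
#' raw binary features (convergence when the relative log-likelihood
#' change drops below 1e-8, at most 100 iterations), with Wald z tests per
#' coefficient and variance inflation factors per feature. An empty
#' selection yields the intercept-only model (intercept = logit of the
#' training prevalence).
#'
#' @param fm a [build_feature_matrix()] result.
#' @param features character vector of selected feature names (subset of
#'   the vocabulary).
#' @param lambda,path optional phase-one metadata carried into the result.
#' @return An object of class `adrd_model`: `features`, `coefficients`
#'   (named, including `(Intercept)`), `se`, `p_values`, `vif`, `lambda`,
#'   `path`, `converged`.
#' @export
logistic_refit <- function(fm, features, lambda = NA_real_, path = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$label
  if (length(setdiff(features, fm$vocabulary))) {
    stop("unknown feature(s): ",
         paste(setdiff(features, fm$vocabulary), collapse = ", "))
  }
  x <- as.matrix(fm$matrix[, features, drop = FALSE])

  if (length(features)) {
    const <- which(apply(x, 2L, function(v) max(v) == min(v)))
    if (length(const)) {
      stop("degenerate (constant) feature column(s): ",
           paste(features[const], collapse = ", "))
    }
    qx <- qr(cbind(1, x))
    if (qx$rank < ncol(x) + 1L) {
      dropped <- setdiff(seq_len(ncol(x) + 1L), qx$pivot[seq_len(qx$rank)]) - 1L
      stop("exactly collinear feature column(s): ",
           paste(features[dropped], collapse = ", "))
    }
  }

  X <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = binomial(),
    control = glm.control(epsilon = 1e-8, maxit = 100L)
  ))
  cf <- fit$coefficients
  if (!fit$converged || any(abs(cf[-1L]) > 20)) {
    worst <- if (length(cf) > 1L) names(which.max(abs(cf[-1L]))) else NULL
    stop("logistic refit failed to converge (possible perfect separation",
         if (!is.null(worst)) paste0("; suspect feature: ", worst), ")")
  }

  # Wald standard errors from the Fisher information at the optimum
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  z <- cf / se
  p <- 2 * pnorm(-abs(z))

  vif <- if (length(features) >= 2L) compute_vif(x) else {
    setNames(rep(NA_real_, length(features)), features)
  }

  structure(
    list(features = features, coefficients = cf, se = se, p_values = p,
         vif = vif, lambda = lambda, path = path,
         converged = fit$converged),
    class = "adrd_model"
  )
}

#' Variance inflation factors of a binary design
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from the least-squares
#' regression of column j on all the other columns plus an intercept.
#' Computed via the inverse of the feature correlation matrix (its diagonal
#' equals the VIFs); on a singular correlation matrix the function falls
#' back to per-column regressions and reports perfectly collinear columns
#' as `Inf` with a warning.
#'
#' @param x numeric matrix of at least two non-constant columns.
#' @return named numeric vector of VIFs (all >= 1 up to rounding).
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("VIF needs at least two features")
  sds <- apply(x, 2L, function(v) stats::sd(v))
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  R <- cor(x)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0)) {
    return(setNames(diag(inv), colnames(x)))
  }
  warning("singular correlation structure: perfectly collinear columns ",
          "reported as Inf")
  vapply(seq_len(ncol(x)), function(j) {
    f <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(f$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L), USE.NAMES = FALSE) |> setNames(colnames(x))
}

#' Two-phase fit: Lasso selection then logistic refit
#'
#' @inheritParams lasso_select
#' @return An `adrd_model` (see [logistic_refit()]).
#' @export
fit_risk_model <- function(fm, config = lasso_config()) {
  sel <- lasso_select(fm, config)
  logistic_refit(fm, sel$selected, lambda = sel$lambda, path = sel$path)
}

#' @export
print.adrd_model <- function(x, ...) {
  cat(sprintf("<adrd_model> %d features (lambda = %s)\n",
              length(x$features),
              if (is.na(x$lambda)) "none" else format(x$lambda, digits = 4)))
  tab <- data.frame(
    coefficient = round(x$coefficients, 4),
    se = round(x$se, 4),
    p_value = signif(x$p_values, 3)
  )
  tab$vif <- round(c(NA_real_, unname(x$vif)), 2)[seq_len(nrow(tab))]
  print(head(tab, 15))
  if (nrow(tab) > 15) cat("  ... and", nrow(tab) - 15, "more rows\n")
  invisible(x)
}

#' @export
coef.adrd_model <- function(object, ...) object$coefficients
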