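# Per-TF essentiality models
#
# Each TF gets its own elastic-net regression mapping perturbation-induced
# protein-activity deltas (features) to measured gene-essentiality
# (depletion) scores across cell lines. More negative essentiality means a
# stronger dependency (DepMap CERES convention). Hyperparameters (penalty
# strength and L1/L2 mix) are chosen by seeded k-fold cross-validation on a
# training split; held-out lines never touch the selection.

#' Train an elastic-net essentiality model for one TF
#'
#' Splits the cell lines into a training fraction and a held-out validation
#' set, standardizes the activity-delta features within the training set,
#' selects the penalty strength and L1 mix by `cv_folds`-fold
#' cross-validated RMSE on the training lines only, refits on all training
#' lines at the chosen hyperparameters, and reports held-out performance.
#' Note the naming: `l1_ratio` is the L1/L2 mix (glmnet's `alpha`) and
#' `alpha` is the penalty strength (glmnet's `lambda`).
#'
#' @param tf TF identifier (metadata only).
#' @param deltas Numeric matrix, cell lines x proteins, of activity deltas
#'   for this TF's knockdown.
#' @param measured Named numeric vector of measured essentiality scores per
#'   cell line (must cover the rows of `deltas`).
#' @param train_fraction Fraction of lines used for training/CV (default
#'   0.75, e.g. a 24-8 split of 32 lines).
#' @param cv_folds Folds for hyperparameter selection (default 4).
#' @param seed Integer seed (split and fold assignment).
#' @param l1_grid Candidate L1 mixes.
#' @param strength_grid Candidate penalty strengths (log-spaced by default).
#' @return Object of class `essentiality_model`: `coefficients` (named, on
#'   the standardized feature scale), `intercept`, `l1_ratio`, `alpha`,
#'   `cv_rmse`, `center`/`scale` (feature standardization), `train_lines`,
#'   `holdout_lines`, `holdout_r`, `holdout_rmse`.
#' @export
train_essentiality_model <- function(tf, deltas, measured,
                                     train_fraction = 0.75, cv_folds = 4L,
                                     seed = 1L,
                                     l1_grid = c(0.1, 0.5, 0.9),
                                     strength_grid = 10^seq(-3, 1,
                                                            length.out = 7)) {
  deltas <- as.matrix(deltas)
  lines <- rownames(deltas)
  if (is.null(lines)) stop("deltas must have cell-line rownames")
  if (!all(lines %in% names(measured)))
    stop("measured scores must cover every cell line")
  # canonical line order: the train/validation split and CV folds depend
  # only on the seed and the line names, not on input row order
  lines <- sort(lines)
  deltas <- deltas[lines, , drop = FALSE]
  y_all <- measured[lines]
  n <- length(lines)
  n_train <- round(train_fraction * n)
  if (n_train < cv_folds) stop("too few training lines for the fold count")
  train <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_train)))
  holdout <- setdiff(seq_len(n), train)
  xtr <- deltas[train, , drop = FALSE]; ytr <- y_all[train]

  center <- colMeans(xtr)
  scale <- apply(xtr, 2, stats::sd)
  scale[scale == 0] <- 1
  xtr_s <- sweep(sweep(xtr, 2, center), 2, scale, "/")

  if (stats::sd(ytr) == 0) {
    warning("constant response for TF ", tf, ": intercept-only model")
    coefs <- stats::setNames(rep(0, ncol(deltas)), colnames(deltas))
    model <- structure(list(tf = tf, coefficients = coefs,
                            intercept = unname(ytr[1]), l1_ratio = NA_real_,
                            alpha = NA_real_, cv_rmse = 0,
                            center = center, scale = scale,
                            train_lines = lines[train],
                            holdout_lines = lines[holdout],
                            holdout_r = NA_real_, holdout_rmse = NA_real_),
                       class = "essentiality_model")
    return(model)
  }

  foldid <- withr::with_seed(as.integer(seed) + 1L,
    sample(rep_len(seq_len(cv_folds), length(train))))
  # penalty strengths are expressed in units of the response scale, so the
  # grid is invariant to rescaling of the essentiality scores
  lambda_grid <- sort(strength_grid, decreasing = TRUE) * stats::sd(ytr)
  best <- list(rmse = Inf)
  for (a in l1_grid) {
    cv <- glmnet::cv.glmnet(xtr_s, ytr, alpha = a, lambda = lambda_grid,
                            foldid = foldid, standardize = FALSE,
                            type.measure = "mse")
    rmse <- sqrt(cv$cvm)
    k <- which.min(rmse)
    if (rmse[k] < best$rmse) {
      best <- list(rmse = rmse[k], l1 = a, lambda = cv$lambda[k])
    }
  }
  fit <- glmnet::glmnet(xtr_s, ytr, alpha = best$l1, lambda = lambda_grid,
                        standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = best$lambda, exact = FALSE))
  coefs <- stats::setNames(beta[-1], colnames(deltas))
  intercept <- beta[1]

  xho_s <- sweep(sweep(deltas[holdout, , drop = FALSE], 2, center),
                 2, scale, "/")
  pred_ho <- intercept + as.numeric(xho_s %*% coefs)
  yho <- y_all[holdout]
  holdout_r <- if (length(holdout) >= 3 && stats::sd(yho) > 0 &&
                   stats::sd(pred_ho) > 0)
    stats::cor(yho, pred_ho) else NA_real_
  structure(list(tf = tf, coefficients = coefs, intercept = intercept,
                 l1_ratio = best$l1, alpha = best$lambda,
                 cv_rmse = best$rmse, center = center, scale = scale,
                 train_lines = lines[train], holdout_lines = lines[holdout],
                 holdout_r = holdout_r,
                 holdout_rmse = sqrt(mean((pred_ho - yho)^2))),
            class = "essentiality_model")
}

#' @export
print.essentiality_model <- function(x, ...) {
  cat(sprintf("<essentiality_model> %s: %d/%d nonzero coefficients, l1_ratio=%s, alpha=%s, cv_rmse=%.4g\n",
              x$tf, sum(x$coefficients != 0), length(x$coefficients),
              format(x$l1_ratio), format(x$alpha), x$cv_rmse))
  invisible(x)
}

#' Predict essentiality scores for new samples
#'
#' Applies the trained affine map (standardization folded in) to new
#' activity-delta rows. Affine in the deltas, so
#' `predict(a + b) = predict(a) + predict(b) - intercept_effective`.
#'
#' @param model An `essentiality_model`.
#' @param deltas Numeric matrix, samples x proteins; columns must cover the
#'   model's protein set (an error lists missing proteins).
#' @return Named numeric vector of predicted scores per sample.
#' @export
predict_essentiality <- function(model, deltas) {
  deltas <- as.matrix(deltas)
  missing <- setdiff(names(model$coefficients), colnames(deltas))
  if (length(missing))
    stop("deltas missing proteins: ",
         paste(utils::head(missing, 10), collapse = ", "))
  x <- deltas[, names(model$coefficients), drop = FALSE]
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  stats::setNames(model$intercept + as.numeric(xs %*% model$coefficients),
                  rownames(deltas))
}

#' Subtype specificity of essentiality scores
#'
#' Per TF, groups scores by subtype, reports group means with standard
#' errors, a Welch one-way test p-value, and the most-dependent subtype
#' (minimum mean score: more negative = more essential). Mean ties are
#' broken lexicographically with a warning; groups with zero variance
#' throughout yield p = 1.
#'
#' @param scores Numeric matrix, TFs x samples, of (predicted or measured)
#'   essentiality.
#' @param labels Named character vector sample -> subtype; at least two
#'   subtypes with two samples each.
#' @return List with `summary` (data frame tf, most_dependent, p) and
#'   `group_stats` (per-TF data frame of subtype, mean, sem, n).
#' @export
subtype_specificity <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (!all(colnames(scores) %in% names(labels)))
    stop("labels must cover every sample")
  labels <- labels[colnames(scores)]
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two subtypes")
  if (any(tab < 2)) stop("every subtype needs at least two samples")
  subs <- sort(names(tab))
  group_stats <- list()
  rows <- list()
  for (tf in rownames(scores)) {
    y <- scores[tf, ]
    gs <- do.call(rbind, lapply(subs, function(s) {
      v <- y[labels == s]
      data.frame(subtype = s, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
    group_stats[[tf]] <- gs
    p <- if (all(vapply(subs, function(s) stats::sd(y[labels == s]),
                        numeric(1)) == 0)) {
      1
    } else {
      tryCatch(stats::oneway.test(y ~ factor(labels))$p.value,
               error = function(e) NA_real_)
    }
    best <- which(gs$mean == min(gs$mean))
    if (length(best) > 1)
      warning("mean tie for TF ", tf, " broken lexicographically")
    rows[[tf]] <- data.frame(tf = tf, most_dependent = gs$subtype[best[1]],
                             p = p, stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, rows), group_stats = group_stats)
}

#' Rank TFs by cross-validated model quality
#'
#' Report table of the per-TF models: inverse CV RMSE (higher = better
#' predicted), held-out correlation, and sparsity.
#'
#' @param models Named list of `essentiality_model`s.
#' @return Data frame sorted by decreasing `inv_cv_rmse`.
#' @export
essentiality_report <- function(models) {
  df <- do.call(rbind, lapply(models, function(m)
    data.frame(tf = m$tf, cv_rmse = m$cv_rmse,
               inv_cv_rmse = ifelse(m$cv_rmse > 0, 1 / m$cv_rmse, Inf),
               holdout_r = m$holdout_r,
               n_nonzero = sum(m$coefficients != 0),
               stringsAsFactors = FALSE)))
  df[order(-df$inv_cv_rmse), , drop = FALSE]
}
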