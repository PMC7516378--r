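# Thermodynamic regulatory model
#
# Each TF j acts on target gene i through a single saturable parameter
# F_ji > 0 (the regulatory capacity):
#   log2 y_i = log2 x_i0 + sum_j log2( (1 + F_ji x_j) / (1 + x_j) )
# F > 1 activates, F < 1 represses, F = 1 is the null. F_ji is the maximum
# fold change TF j can induce on gene i (the x -> Inf saturation limit).

# One fold-change term per regulator, vectorized over samples.
# g: log2 F (length r), x: r x K matrix of regulator expression.
fold_change_log2 <- function(g, x) {
  f <- 2^g
  log2((1 + f * x) / (1 + x))
}

#' Predict expression under the thermodynamic model
#'
#' Evaluates the forward model for every target gene in `fvals` given
#' regulator (TF) expression: per gene and sample,
#' `log2 yhat = log2 basal + sum_j log2((1 + F_j x_j) / (1 + x_j))`.
#'
#' @param fvals An [f_matrix] of fitted (or ground-truth) parameters.
#' @param tf_expr Numeric matrix of nonnegative TF expression, TFs in rows
#'   (rownames are TF ids), samples in columns. Must cover every TF with an
#'   edge in `fvals`.
#' @return Numeric matrix (target genes x samples) of nonnegative predicted
#'   expression on the linear scale.
#' @export
predict_expression <- function(fvals, tf_expr) {
  tf_expr <- as.matrix(tf_expr)
  need <- f_tfs(fvals)
  missing <- setdiff(need, rownames(tf_expr))
  if (length(missing))
    stop("missing TF expression for: ", paste(missing, collapse = ", "))
  if (any(tf_expr[need, ] < 0)) stop("TF expression must be nonnegative")
  by_gene <- f_by_gene(fvals)
  genes <- names(fvals$basal)
  out <- matrix(NA_real_, length(genes), ncol(tf_expr),
                dimnames = list(genes, colnames(tf_expr)))
  for (gn in genes) {
    ed <- by_gene[[gn]]
    lp <- log2(fvals$basal[[gn]])
    if (!is.null(ed) && nrow(ed)) {
      x <- tf_expr[ed$tf, , drop = FALSE]
      lp <- lp + colSums(fold_change_log2(ed$log2f, x))
    }
    out[gn, ] <- 2^lp
  }
  out
}

#' Penalized least-squares objective of the regulatory model
#'
#' Sum over samples and fitted genes of squared log2 residuals plus an
#' L2-like penalty on log2 F:
#' `sum_k sum_i (log2 yhat_ik - log2 y_ik)^2 + lambda * sum_edges (log2 F)^2`.
#' Basal levels are not penalized.
#'
#' @param fvals An [f_matrix].
#' @param observed An [expression_set] (or matrix) holding the observed
#'   expression of the fitted target genes and of all regulator TFs. Target
#'   values must be strictly positive (pseudocount policy is applied upstream
#'   by [fit_subtype_model]).
#' @param lambda Nonnegative penalty strength.
#' @return Nonnegative scalar objective value.
#' @export
model_objective <- function(fvals, observed, lambda = 0) {
  stopifnot(lambda >= 0)
  vals <- expr_values(observed)
  genes <- names(fvals$basal)
  if (!all(genes %in% rownames(vals)))
    stop("observed expression missing fitted genes")
  y <- vals[genes, , drop = FALSE]
  if (any(y <= 0))
    stop("observed expression must be strictly positive for fitted genes")
  pred <- predict_expression(fvals, vals)
  sum((log2(pred[genes, , drop = FALSE]) - log2(y))^2) +
    lambda * sum(fvals$edges$log2f^2)
}

# Fit one target gene: minimize the penalized objective over
# (log2 basal, log2 F vector) with L-BFGS-B and analytic gradients.
# y: K-vector of positive observed values; x: r x K regulator expression.
fit_gene <- function(y, x, lambda, max_iter = 500L, grad_tol = 1e-6) {
  ly <- log2(y)
  r <- if (is.null(x)) 0L else nrow(x)
  if (r == 0L) {
    return(list(log2_basal = mean(ly), log2f = numeric(0), converged = TRUE))
  }
  theta0 <- c(mean(ly), rep(0, r))
  fn <- function(th) {
    pred <- th[1] + colSums(fold_change_log2(th[-1], x))
    sum((pred - ly)^2) + lambda * sum(th[-1]^2)
  }
  gr <- function(th) {
    g <- th[-1]
    fx <- 2^g * x
    pred <- th[1] + colSums(log2((1 + fx) / (1 + x)))
    res <- pred - ly
    # d pred_k / d g_j = F_j x_jk / (1 + F_j x_jk)
    dg <- 2 * as.numeric((fx / (1 + fx)) %*% res) + 2 * lambda * g
    c(2 * sum(res), dg)
  }
  fit <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = grad_tol,
                                     factr = 10))
  list(log2_basal = fit$par[1], log2f = fit$par[-1],
       converged = fit$convergence == 0L)
}

#' Fit configuration for the per-subtype regression
#'
#' @param lambda Nonnegative L2-like penalty strength on log2 F (default 0.1,
#'   the value selected by cross-validation in the reference analysis).
#' @param max_iter Maximum quasi-Newton iterations per gene.
#' @param grad_tol Projected-gradient tolerance for convergence.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lambda = 0.1, max_iter = 500L, grad_tol = 1e-6,
                       folds = 5L, seed = 1L) {
  stopifnot(lambda >= 0, folds >= 2)
  structure(list(lambda = lambda, max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit the regulatory model for one subtype
#'
#' Fits the thermodynamic model gene by gene to all samples carrying the
#' given subtype label. Per target gene the penalized objective is minimized
#' over (log2 basal, log2 F) by L-BFGS-B with analytic gradients, initialized
#' at log2 F = 0 (no regulation) and log2 basal = mean log2 expression.
#' Optimizing log2 F makes F > 0 structural. Genes without candidate
#' regulators get a basal-only fit. Per-gene fits are independent.
#'
#' @param backbone A [candidate_network] of TF-to-gene edges.
#' @param expr An [expression_set]. Zeros in observed target rows are
#'   replaced by 1 before log2 (pseudocount policy).
#' @param subtype Subtype label selecting samples, or `NULL` for all samples.
#' @param config A [fit_config].
#' @return A list of class `fit_result` with elements `fvals` ([f_matrix]),
#'   `train_error` (unpenalized mean squared log2 residual),
#'   `converged_genes` (fraction), `n_samples`, and `samples`.
#' @export
fit_subtype_model <- function(backbone, expr, subtype = NULL,
                              config = fit_config()) {
  vals <- expr_values(expr)
  if (!is.null(subtype)) {
    if (is.null(expr$subtype)) stop("expression has no subtype labels")
    samples <- colnames(vals)[expr$subtype == subtype]
  } else samples <- colnames(vals)
  if (length(samples) < 2) stop("need at least 2 samples to fit")
  vals <- vals[, samples, drop = FALSE]

  net <- backbone[backbone$tf %in% rownames(vals) &
                    backbone$gene %in% rownames(vals), , drop = FALSE]
  genes <- sort(unique(net$gene))
  by_gene <- split(net, net$gene)

  edges_out <- vector("list", length(genes))
  basal <- numeric(length(genes)); names(basal) <- genes
  conv <- logical(length(genes)); names(conv) <- genes
  sq_err <- 0; n_obs <- 0
  for (i in seq_along(genes)) {
    gn <- genes[i]
    ed <- by_gene[[gn]]
    y <- vals[gn, ]
    y[y == 0] <- 1
    x <- vals[ed$tf, , drop = FALSE]
    fit <- fit_gene(y, x, config$lambda, config$max_iter, config$grad_tol)
    basal[gn] <- 2^fit$log2_basal
    conv[gn] <- fit$converged
    edges_out[[i]] <- data.frame(tf = ed$tf, gene = gn, log2f = fit$log2f,
                                 stringsAsFactors = FALSE)
    pred <- fit$log2_basal + colSums(fold_change_log2(fit$log2f, x))
    sq_err <- sq_err + sum((pred - log2(y))^2)
    n_obs <- n_obs + length(y)
  }
  edges <- do.call(rbind, edges_out)
  structure(list(
    fvals = f_matrix(edges, basal, subtype = if (is.null(subtype)) "all" else subtype,
                     lambda = config$lambda, converged = conv),
    train_error = if (n_obs) sq_err / n_obs else 0,
    converged_genes = if (length(conv)) mean(conv) else 1,
    n_samples = length(samples),
    samples = samples), class = "fit_result")
}

#' Symmetric mean absolute percentage error
#'
#' `mean( 2 |yhat - y| / (|y| + |yhat|) )` with the 0/0 case defined as 0.
#' Bounded on \[0, 2\].
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Scalar sMAPE.
#' @export
smape <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  denom <- abs(observed) + abs(predicted)
  term <- ifelse(denom == 0, 0, 2 * abs(predicted - observed) / denom)
  mean(term)
}

#' Cross-validate the penalty strength lambda
#'
#' Sample-wise k-fold cross-validation within one subtype: for each lambda
#' the model is refit on the training folds and held-out samples are
#' predicted from their own TF expression; the per-gene sMAPE of pooled
#' held-out predictions is averaged across genes. When a known TF-TF
#' interaction reference is supplied, the precision-recall AUC of
#' co-regulation recovery (computed from a full-data fit at each lambda via
#' [all_pairs_coregulation]) is reported alongside.
#'
#' @param backbone A [candidate_network].
#' @param expr An [expression_set].
#' @param subtype Subtype label (or `NULL` for all samples).
#' @param lambda_grid Numeric vector of candidate penalties (default includes
#'   0.1, the reference choice).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param reference Optional set of known interacting TF pairs (see
#'   [interaction_reference]).
#' @return Data frame with columns `lambda`, `cv_smape`, `pr_auc`, plus
#'   attributes `best_smape` and `best_pr_auc` (selected lambdas).
#' @export
cross_validate_lambda <- function(backbone, expr, subtype = NULL,
                                  lambda_grid = c(0.01, 0.1, 1, 10),
                                  folds = 5L, seed = 1L, reference = NULL) {
  if (!length(lambda_grid)) stop("lambda grid must be non-empty")
  vals <- expr_values(expr)
  samples <- if (!is.null(subtype)) colnames(vals)[expr$subtype == subtype]
             else colnames(vals)
  if (folds > length(samples)) stop("more folds than samples")
  fold_id <- withr::with_seed(seed,
    sample(rep_len(seq_len(folds), length(samples))))
  names(fold_id) <- samples

  cv_smape <- pr_auc <- rep(NA_real_, length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    cfg <- fit_config(lambda = lambda_grid[li], seed = seed, folds = folds)
    genes <- NULL; obs_all <- NULL; pred_all <- NULL
    for (k in seq_len(folds)) {
      train <- samples[fold_id != k]; test <- samples[fold_id == k]
      sub_expr <- expression_set(vals[, train, drop = FALSE])
      fit <- fit_subtype_model(backbone, sub_expr, NULL, cfg)
      pred <- predict_expression(fit$fvals, vals[, test, drop = FALSE])
      obs <- vals[rownames(pred), test, drop = FALSE]
      obs_all <- cbind(obs_all, obs); pred_all <- cbind(pred_all, pred)
    }
    per_gene <- vapply(seq_len(nrow(obs_all)), function(i)
      smape(obs_all[i, ], pred_all[i, ]), numeric(1))
    cv_smape[li] <- mean(per_gene)
    if (!is.null(reference)) {
      full <- fit_subtype_model(backbone,
                                expression_set(vals[, samples, drop = FALSE]),
                                NULL, cfg)
      corr <- all_pairs_coregulation(full$fvals, seed = seed)
      pr_auc[li] <- interaction_pr_auc(corr, reference)
    }
  }
  out <- data.frame(lambda = lambda_grid, cv_smape = cv_smape, pr_auc = pr_auc)
  attr(out, "best_smape") <- lambda_grid[which.min(cv_smape)]
  attr(out, "best_pr_auc") <- if (all(is.na(pr_auc))) NA_real_
                              else lambda_grid[which.max(pr_auc)]
  out
}

#' Inter-subtype prediction error matrix
#'
#' Cross-applies every subtype's fitted model to every subtype's cohort:
#' entry (row r, column c) is the median sMAPE over the `top_n_variable`
#' most variable genes of cohort r when predicted by model c, min-max scaled
#' within each row to \[0, 1\]. A matched model/cohort pair should sit at the
#' row minimum when regulation is genuinely subtype-specific.
#'
#' @param models Named list of [f_matrix] objects, one per subtype.
#' @param cohorts Named list of [expression_set]s (same names).
#' @param top_n_variable Number of most-variable genes (by log2 variance in
#'   the row cohort, among the model's target genes) used per entry.
#' @return List with `scaled` and `raw` subtype-by-subtype matrices.
#' @export
inter_subtype_prediction_matrix <- function(models, cohorts,
                                            top_n_variable = 50L) {
  subs <- names(models)
  if (is.null(subs) || !setequal(subs, names(cohorts)))
    stop("models and cohorts must share subtype names")
  subs <- sort(subs)
  raw <- matrix(NA_real_, length(subs), length(subs),
                dimnames = list(cohort = subs, model = subs))
  for (r in subs) {
    vals <- expr_values(cohorts[[r]])
    genes <- intersect(names(models[[subs[1]]]$basal), rownames(vals))
    for (cc in subs)
      genes <- intersect(genes, names(models[[cc]]$basal))
    v <- apply(log2(pmax(vals[genes, , drop = FALSE], 1e-12)), 1, stats::var)
    top <- genes[order(v, decreasing = TRUE)][seq_len(min(top_n_variable, length(genes)))]
    for (cc in subs) {
      pred <- predict_expression(models[[cc]], vals)
      per_gene <- vapply(top, function(g) smape(vals[g, ], pred[g, ]), numeric(1))
      raw[r, cc] <- stats::median(per_gene)
    }
  }
  scaled <- t(apply(raw, 1, function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0, length(x)) else (x - min(x)) / rng
  }))
  dimnames(scaled) <- dimnames(raw)
  list(scaled = scaled, raw = raw)
}
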