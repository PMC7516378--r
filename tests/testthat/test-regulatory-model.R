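test_that("the forward predictor matches hand evaluations and limits", {
  fv <- make_fvals("T1", "G1", log2f = 0, basal = 10, basal_genes = "G1")
  x <- matrix(c(0.5, 1, 7), 1, 3, dimnames = list("T1", c("a", "b", "c")))
  # F = 1: no regulatory effect, prediction at basal everywhere
  expect_equal(unname(predict_expression(fv, x)["G1", ]), rep(10, 3))

  # basal 10, x = 1, F = 4 -> 10 * (1 + 4)/(1 + 1) = 25
  fv4 <- make_fvals("T1", "G1", log2f = 2, basal = 10, basal_genes = "G1")
  x1 <- matrix(1, 1, 1, dimnames = list("T1", "s"))
  expect_equal(unname(predict_expression(fv4, x1)["G1", 1]), 25)

  # repression saturates at basal * F: F = 0.25, x -> Inf
  fvr <- make_fvals("T1", "G1", log2f = -2, basal = 10, basal_genes = "G1")
  xb <- matrix(1e8, 1, 1, dimnames = list("T1", "s"))
  expect_equal(unname(predict_expression(fvr, xb)["G1", 1]), 2.5,
               tolerance = 1e-6)

  # missing TF row errors and names the TF
  expect_error(predict_expression(fv4, matrix(1, 1, 1,
                                              dimnames = list("T9", "s"))),
               "T1")
})

test_that("the objective matches hand computation and penalty monotonicity", {
  # perfect fit with all F = 1 gives zero
  fv <- make_fvals(c("T1", "T1"), c("G1", "G2"), c(0, 0),
                   basal_genes = c("G1", "G2"), basal = c(8, 2))
  obs <- rbind(G1 = c(8, 8), G2 = c(2, 2), T1 = c(1, 3))
  colnames(obs) <- c("s1", "s2")
  expect_equal(model_objective(fv, obs, lambda = 0), 0)
  expect_equal(model_objective(fv, obs, lambda = 10), 0)  # F=1 unpenalized

  # hand-computed two-gene case at lambda = 0
  fv2 <- make_fvals(c("T1", "T1"), c("G1", "G2"), c(1, -1),
                    basal_genes = c("G1", "G2"), basal = c(8, 2))
  x <- obs["T1", ]
  pred_g1 <- log2(8) + log2((1 + 2 * x) / (1 + x))
  pred_g2 <- log2(2) + log2((1 + 0.5 * x) / (1 + x))
  expected <- sum((pred_g1 - log2(obs["G1", ]))^2) +
    sum((pred_g2 - log2(obs["G2", ]))^2)
  expect_equal(model_objective(fv2, obs, 0), expected)
  # larger lambda strictly increases the objective when any F != 1
  expect_gt(model_objective(fv2, obs, 1), model_objective(fv2, obs, 0.1))
  expect_error(model_objective(fv2, rbind(obs * 0, T1 = x), 0), "positive")
})

test_that("analytic gradients agree with finite differences", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      r <- sample(2:4, 1); K <- 12
      x <- matrix(2^rnorm(r * K), r, K)
      y <- 2^rnorm(K, 3, 1)
      lambda <- runif(1, 0, 1)
      theta <- c(rnorm(1, 3, 0.5), rnorm(r, 0, 1))
      fn <- function(th) {
        pred <- th[1] + colSums(log2((1 + 2^th[-1] * x) / (1 + x)))
        sum((pred - log2(y))^2) + lambda * sum(th[-1]^2)
      }
      gr_analytic <- local({
        g <- theta[-1]; fx <- 2^g * x
        pred <- theta[1] + colSums(log2((1 + fx) / (1 + x)))
        res <- pred - log2(y)
        c(2 * sum(res),
          2 * as.numeric((fx / (1 + fx)) %*% res) + 2 * lambda * g)
      })
      eps <- 1e-6
      gr_num <- vapply(seq_along(theta), function(i) {
        tp <- theta; tm <- theta
        tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
        (fn(tp) - fn(tm)) / (2 * eps)
      }, numeric(1))
      expect_equal(gr_analytic, gr_num, tolerance = 1e-5)
    }
  })
})

test_that("fitting recovers a null system and shrinks with lambda", {
  # all F = 1, no noise: fitted |log2 F| < 0.05 under lambda = 0.1
  truth <- generate_regulatory_truth(3, 8, "A", edge_density = 0.6,
                                     noise_sd = 0, seed = 13)
  truth$f$log2f <- 0
  expr <- simulate_cohort(truth, 40, seed = 14)
  bb <- candidate_network(truth$backbone$tf, truth$backbone$gene)
  fit <- fit_subtype_model(bb, expr, "A", fit_config(lambda = 0.1))
  expect_lt(max(abs(fit$fvals$edges$log2f)), 0.05)
  expect_equal(fit$converged_genes, 1)

  # shrinkage sweep: mean |log2 F| non-increasing in lambda
  truth2 <- generate_regulatory_truth(3, 8, "A", edge_density = 0.6,
                                      noise_sd = 0.1, seed = 15)
  expr2 <- simulate_cohort(truth2, 40, seed = 16)
  bb2 <- candidate_network(truth2$backbone$tf, truth2$backbone$gene)
  mags <- vapply(c(0.01, 0.1, 1, 10), function(l)
    mean(abs(fit_subtype_model(bb2, expr2, "A",
                               fit_config(lambda = l))$fvals$edges$log2f)),
    numeric(1))
  expect_true(all(diff(mags) <= 1e-8))
})

test_that("genes without regulators get a basal-only fit", {
  bb <- candidate_network("T1", "G1")
  expr <- make_expr_matrix(c("T1", "G1"), 10, seed = 3)
  fit <- fit_subtype_model(bb, expr, NULL, fit_config())
  expect_named(fit$fvals$basal, "G1")
  bb2 <- candidate_network(c("T1", "T9"), c("G1", "G2"))  # T9 unmeasured
  fit2 <- fit_subtype_model(bb2, expr, NULL, fit_config())
  expect_false("G2" %in% names(fit2$fvals$basal))
})

test_that("sMAPE follows its definition and degenerate rules", {
  expect_equal(smape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(smape(1, 3), 1.0)          # 2*2/4
  expect_equal(smape(0, 0), 0)            # 0/0 := 0
  expect_equal(smape(c(0, 1), c(0, 3)), 0.5)
  expect_error(smape(1:3, 1:2), "length")
  withr::with_seed(5, {
    y <- runif(50); p <- runif(50)
    expect_true(smape(y, p) >= 0 && smape(y, p) <= 2)
  })
})

test_that("cross-validation selects small lambda on noiseless data", {
  truth <- generate_regulatory_truth(3, 6, "A", edge_density = 0.6,
                                     noise_sd = 0, seed = 41)
  expr <- simulate_cohort(truth, 30, seed = 42)
  bb <- candidate_network(truth$backbone$tf, truth$backbone$gene)
  cv <- cross_validate_lambda(bb, expr, "A", lambda_grid = c(0.01, 1, 10),
                              folds = 3, seed = 1)
  expect_equal(attr(cv, "best_smape"), 0.01)
  expect_true(all(diff(cv$cv_smape) > 0))
  # the default grid includes the reference penalty 0.1
  expect_true(0.1 %in% eval(formals(cross_validate_lambda)$lambda_grid))
  expect_error(cross_validate_lambda(bb, expr, "A", 0.1, folds = 1000), "folds")
})

test_that("identical data in all folds gives equal per-fold errors", {
  # build a cohort where each fold sees the same sample values
  vals <- make_expr_matrix(c("T1", "G1"), 2, seed = 8)
  vals <- vals[, c(1, 1, 2, 2, 1, 1, 2, 2)]
  colnames(vals) <- sprintf("s%d", 1:8)
  bb <- candidate_network("T1", "G1")
  # folds of equal composition -> identical held-out error per fold
  cfg_err <- vapply(1:2, function(k) {
    train <- if (k == 1) c(1, 2, 3, 4) else c(5, 6, 7, 8)
    test <- setdiff(1:8, train)
    fit <- fit_subtype_model(bb, expression_set(vals[, train]), NULL,
                             fit_config(lambda = 0.1))
    pred <- predict_expression(fit$fvals, vals[, test, drop = FALSE])
    smape(vals["G1", test], pred["G1", ])
  }, numeric(1))
  expect_equal(cfg_err[1], cfg_err[2])
})

test_that("the inter-subtype matrix is diagonal-dominant and relabels cleanly", {
  truth <- generate_regulatory_truth(4, 12, c("A", "B"), 0.5,
                                     frac_signature_edges = 0.5,
                                     noise_sd = 0.05, seed = 51)
  expr <- simulate_cohort(truth, 40, seed = 52)
  bb <- candidate_network(truth$backbone$tf, truth$backbone$gene)
  models <- lapply(c(A = "A", B = "B"), function(s)
    fit_subtype_model(bb, expr, s, fit_config(lambda = 0.1))$fvals)
  cohorts <- lapply(c(A = "A", B = "B"), function(s)
    expr_subset(expr, names(expr$subtype)[expr$subtype == s]))
  m <- inter_subtype_prediction_matrix(models, cohorts, top_n_variable = 12)
  expect_equal(unname(diag(m$scaled)), c(0, 0))  # matched model = row minimum
  expect_equal(dim(m$raw), c(2, 2))

  # permuting subtype order permutes rows/columns consistently
  m2 <- inter_subtype_prediction_matrix(rev(models), rev(cohorts),
                                        top_n_variable = 12)
  expect_equal(m2$raw, m$raw)

  # single subtype: 1x1 scaled zero
  m1 <- inter_subtype_prediction_matrix(models["A"], cohorts["A"], 5)
  expect_equal(unname(m1$scaled[1, 1]), 0)
  expect_error(inter_subtype_prediction_matrix(models, cohorts["A"], 5),
               "share")
})
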