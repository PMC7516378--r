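named_vec <- function(x, prefix = "g") {
  stats::setNames(x, sprintf("%s%03d", prefix, seq_along(x)))
}

test_that("robust correlation handles clean, degenerate and outlier inputs", {
  # identical profiles of length 10 -> exactly 1
  v <- named_vec(c(1.2, -0.8, 2, 0.5, -1.5, 0.9, 1.1, -2, 0.7, 1.6))
  expect_equal(ransac_correlation(v, v, seed = 1), 1.0)

  # only 3 shared regulated targets -> exactly 0
  a <- named_vec(c(1, -1, 2, 0.01, 0.02))
  b <- named_vec(c(2, -2, 1, 3, 3))
  expect_identical(ransac_correlation(a, b, seed = 1), 0)

  # constant input -> 0
  cst <- named_vec(rep(1, 10))
  expect_identical(ransac_correlation(cst, v, seed = 1), 0)

  # gross outliers are rejected: r within 0.05 of the clean-point Pearson
  withr::with_seed(71, {
    x <- runif(50, -3, 3)
    x[abs(x) < 0.15] <- 0.5
    y <- 2 * x + rnorm(50, 0, 0.1)
    out <- sample(50, 5)
    y[out] <- y[out] + 10
    xv <- named_vec(x); yv <- named_vec(y)
    r_clean <- cor(x[-out], y[-out])
    expect_lt(abs(ransac_correlation(xv, yv, seed = 7) - r_clean), 0.05)
  })
})

test_that("robust correlation is invariant to common affine transforms", {
  withr::with_seed(72, {
    x <- named_vec(runif(30, 0.2, 2.5) * sample(c(-1, 1), 30, TRUE))
    y <- named_vec(as.numeric(x) * 1.3 + rnorm(30, 0, 0.2))
    names(y) <- names(x)
    r1 <- ransac_correlation(x, y, seed = 3)
    # same positive affine map applied to both vectors (regulated set fixed)
    r2 <- ransac_correlation(x * 2, y * 2, seed = 3)
    expect_equal(r1, r2, tolerance = 1e-9)
  })
})

test_that("all-pairs co-regulation matches a pairwise loop and is symmetric", {
  truth <- generate_regulatory_truth(4, 25, "A", edge_density = 0.8,
                                     noise_sd = 0, seed = 73)
  fv <- truth_f_matrix(truth, "A")
  corr <- all_pairs_coregulation(fv, seed = 11)
  expect_equal(corr$r, t(corr$r))
  expect_equal(corr$n_shared, t(corr$n_shared))
  tfs <- rownames(corr$r)
  profiles <- lapply(tfs, function(tf) {
    ed <- fv$edges[fv$edges$tf == tf, ]
    stats::setNames(ed$log2f, ed$gene)
  })
  names(profiles) <- tfs
  pair_id <- 0L
  for (i in seq_along(tfs)) for (j in i:length(tfs)) {
    pair_id <- pair_id + 1L
    expect_equal(corr$r[i, j],
                 ransac_correlation(profiles[[i]], profiles[[j]],
                                    seed = 11 + pair_id))
  }
  # a TF regulating > 3 targets correlates 1 with itself
  expect_true(all(diag(corr$r)[diag(corr$n_shared) > 3] == 1))
})

test_that("disjoint regulons give zero correlation and zero shared targets", {
  ed <- data.frame(tf = rep(c("T1", "T2"), each = 4),
                   gene = sprintf("g%d", 1:8),
                   log2f = rep(c(1, -1), 4))
  fv <- f_matrix(ed, stats::setNames(rep(10, 8), sprintf("g%d", 1:8)))
  corr <- all_pairs_coregulation(fv, seed = 1)
  expect_equal(corr$r["T1", "T2"], 0)
  expect_equal(corr$n_shared["T1", "T2"], 0)
})

test_that("interaction enrichment reproduces the cross-product odds ratio", {
  # synthetic correlation matrix with a known contingency layout
  withr::with_seed(74, {
    n_tf <- 20
    tfs <- sprintf("T%02d", 1:n_tf)
    r <- matrix(0, n_tf, n_tf, dimnames = list(tfs, tfs))
    ns <- matrix(10L, n_tf, n_tf, dimnames = list(tfs, tfs))
    pairs <- which(upper.tri(r), arr.ind = TRUE)
    r[upper.tri(r)] <- runif(nrow(pairs))
    r <- r + t(r); diag(r) <- 1
    corr <- structure(list(r = r, n_shared = ns),
                      class = "correlation_matrix")
    ref <- interaction_reference(tfs[pairs[1:40, 1]], tfs[pairs[1:40, 2]])
    enr <- interaction_enrichment(corr, ref, top_fraction = 0.1)
    tab <- enr$table
    expect_equal(enr$odds_ratio,
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
    expect_equal(enr$p_value, oracle_fisher_two_sided(tab), tolerance = 1e-9)
    expect_equal(sum(tab), nrow(pairs))

    # reference covering all pairs: degenerate, p = 1
    ref_all <- interaction_reference(tfs[pairs[, 1]], tfs[pairs[, 2]])
    enr_all <- interaction_enrichment(corr, ref_all, top_fraction = 0.1)
    expect_equal(enr_all$p_value, 1)
    expect_true(is.na(enr_all$odds_ratio) || is.infinite(enr_all$odds_ratio))
    expect_error(interaction_enrichment(corr,
                                        structure(list(pairs = character(0)),
                                                  class = "interaction_reference"),
                                        0.1),
                 "empty")
  })
})

test_that("the worked 2x2 example gives odds ratio 11 and the exact p", {
  # table [[10, 90], [40, 3960]]
  tab <- matrix(c(10, 90, 40, 3960), 2, 2, byrow = TRUE)
  or <- (10 * 3960) / (90 * 40)
  expect_equal(or, 11.0)
  expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_two_sided(tab),
               tolerance = 1e-9)
})

test_that("enrichment p-values are calibrated under a random null", {
  withr::with_seed(75, {
    n_pairs <- 100
    hits <- 0
    n_sim <- 500
    for (i in seq_len(n_sim)) {
      top <- sample(c(rep(TRUE, 10), rep(FALSE, 90)))
      pos <- sample(c(rep(TRUE, 20), rep(FALSE, 80)))
      tab <- matrix(c(sum(top & pos), sum(top & !pos),
                      sum(!top & pos), sum(!top & !pos)), 2, 2, byrow = TRUE)
      if (stats::fisher.test(tab)$p.value <= 0.05) hits <- hits + 1
    }
    # conservative exact test: type-I error at or below alpha, within
    # binomial uncertainty of 0.05
    ci_hi <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim)
    expect_lt(hits / n_sim, ci_hi)
  })
})

test_that("PR-AUC matches brute-force enumeration and known baselines", {
  # perfect ranking -> AUC 1
  tfs <- sprintf("T%02d", 1:10)
  r <- matrix(0, 10, 10, dimnames = list(tfs, tfs))
  ns <- matrix(10L, 10, 10, dimnames = list(tfs, tfs))
  pr <- which(upper.tri(r), arr.ind = TRUE)
  withr::with_seed(76, {
    pos_idx <- sample(nrow(pr), 8)
    vals <- runif(nrow(pr), 0, 0.4)
    vals[pos_idx] <- runif(8, 0.6, 1)
    r[upper.tri(r)] <- vals
    r <- r + t(r); diag(r) <- 1
    corr <- structure(list(r = r, n_shared = ns),
                      class = "correlation_matrix")
    ref <- interaction_reference(tfs[pr[pos_idx, 1]], tfs[pr[pos_idx, 2]])
    expect_equal(interaction_pr_auc(corr, ref), 1)

    # brute-force threshold oracle on 20 scored pairs
    scores <- runif(20)
    labels <- sample(c(TRUE, FALSE), 20, TRUE)
    if (!any(labels)) labels[1] <- TRUE
    expect_equal(regcap:::pr_auc(scores, labels),
                 oracle_pr_auc(scores, labels), tolerance = 1e-12)

    # random ranking: AUC ~ positive fraction
    aucs <- replicate(200, {
      s <- runif(40); l <- c(rep(TRUE, 10), rep(FALSE, 30))
      regcap:::pr_auc(s, l)
    })
    expect_lt(abs(mean(aucs) - 0.25), 0.05)
    expect_error(interaction_pr_auc(corr,
                                    interaction_reference("Z1", "Z2")),
                 "positive")
  })
})

test_that("independent random profiles rarely correlate strongly", {
  withr::with_seed(77, {
    n <- 0; strong <- 0
    for (i in 1:150) {
      x <- named_vec(runif(50, 0.2, 2.5) * sample(c(-1, 1), 50, TRUE))
      y <- named_vec(runif(50, 0.2, 2.5) * sample(c(-1, 1), 50, TRUE))
      n <- n + 1
      if (abs(ransac_correlation(x, y, seed = i)) > 0.8) strong <- strong + 1
    }
    expect_lt(strong / n, 0.01)
  })
})
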