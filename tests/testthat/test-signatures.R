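# Shared small cohort for permutation determinism tests (kept compact so
# the repeated refits stay fast).
sig_fixture <- local({
  truth <- generate_regulatory_truth(4, 10, c("A", "B"), 0.5,
                                     frac_signature_edges = 0.25,
                                     noise_sd = 0.1, seed = 101)
  expr <- simulate_cohort(truth, 30, seed = 102)
  bb <- candidate_network(truth$backbone$tf, truth$backbone$gene)
  cfg <- fit_config(lambda = 0.1)
  models <- lapply(c(A = "A", B = "B"), function(s)
    fit_subtype_model(bb, expr, s, cfg)$fvals)
  list(truth = truth, expr = expr, bb = bb, cfg = cfg, models = models)
})

test_that("the permutation null is reproducible and exchangeable-consistent", {
  fx <- sig_fixture
  n1 <- permute_and_refit(fx$bb, fx$expr, n_shuffles = 3, seed = 5,
                          config = fx$cfg)
  n2 <- permute_and_refit(fx$bb, fx$expr, n_shuffles = 3, seed = 5,
                          config = fx$cfg)
  expect_identical(n1, n2)
  expect_equal(n1$n_shuffles, 3)
  expect_true(all(is.finite(n1$stats$null_sd)))
  expect_true(all(n1$stats$null_sd >= 0))
  expect_error(permute_and_refit(fx$bb, fx$expr, n_shuffles = 1), "at least 2")

  # identical generative F across subtypes: the unshuffled fit is a draw
  # from the shuffle distribution, so deviations stay within a few SE
  truth0 <- generate_regulatory_truth(3, 8, c("A", "B"), 0.6,
                                      frac_signature_edges = 0,
                                      noise_sd = 0.1, seed = 103)
  expr0 <- simulate_cohort(truth0, 25, seed = 104)
  bb0 <- candidate_network(truth0$backbone$tf, truth0$backbone$gene)
  null0 <- permute_and_refit(bb0, expr0, n_shuffles = 10, seed = 6,
                             config = fx$cfg)
  models0 <- lapply(c(A = "A", B = "B"), function(s)
    fit_subtype_model(bb0, expr0, s, fx$cfg)$fvals)
  obs <- do.call(rbind, Map(function(m, s)
    data.frame(tf = m$edges$tf, gene = m$edges$gene, subtype = s,
               log2f = m$edges$log2f), models0, names(models0)))
  key <- function(d) paste(d$tf, d$gene, d$subtype)
  i <- match(key(obs), key(null0$stats))
  z <- abs(obs$log2f - null0$stats$null_mean[i]) /
    pmax(null0$stats$null_sd[i], 1e-6)
  expect_lt(stats::median(z), 3)
})

test_that("signature calling respects the SD-threshold boundary rules", {
  null <- structure(list(stats = data.frame(
    tf = "T1", gene = c("g1", "g2", "g3"), subtype = "A",
    null_mean = c(0, 0, 1), null_sd = c(0.2, 0, 0.1),
    stringsAsFactors = FALSE), n_shuffles = 30),
    class = "permutation_null")
  fv <- list(A = make_fvals(rep("T1", 3), c("g1", "g2", "g3"),
                            c(1.0, 0, 1.2)))
  # g1: deviation exactly 5 SD -> flagged (inclusive rule)
  # g2: zero SD, zero deviation -> never flagged
  # g3: deviation 2 SD -> not flagged
  calls <- call_signature_edges(fv, null, sd_threshold = 5)
  expect_identical(calls$gene, "g1")
  expect_gte(calls$z, 5)
  # null must cover all edges
  fv_extra <- list(A = make_fvals("T1", "g9", 2))
  expect_error(call_signature_edges(fv_extra, null), "cover")
})

test_that("planted signature edges are recovered with few false calls", {
  # a cohort sized so the 5-SD permutation rule has power: the shuffle SD
  # of a mixed-label fit shrinks as 1/sqrt(N), so detection needs a few
  # hundred samples per subtype
  truth <- generate_regulatory_truth(4, 12, c("A", "B", "C"), 0.4,
                                     frac_signature_edges = 0.2,
                                     noise_sd = 0.1, seed = 121)
  expr <- simulate_cohort(truth, 300, seed = 122)
  bb <- candidate_network(truth$backbone$tf, truth$backbone$gene)
  cfg <- fit_config(lambda = 0.1)
  models <- lapply(c(A = "A", B = "B", C = "C"), function(s)
    fit_subtype_model(bb, expr, s, cfg)$fvals)
  null <- permute_and_refit(bb, expr, n_shuffles = 30, seed = 7,
                            config = cfg)
  calls <- call_signature_edges(models, null, sd_threshold = 5)
  truth_key <- paste(truth$signature$tf, truth$signature$gene,
                     truth$signature$subtype)
  call_key <- paste(calls$tf, calls$gene, calls$subtype)
  expect_gte(mean(truth_key %in% call_key), 0.8)
  # false positives among never-planted edges are rare
  planted_edges <- paste(truth$signature$tf, truth$signature$gene)
  fp <- calls[!(paste(calls$tf, calls$gene) %in% planted_edges), ]
  n_edges <- nrow(truth$backbone) * length(truth$subtypes)
  expect_lte(nrow(fp) / n_edges, 0.01)
})

test_that("participation scores count signature edges per subtype", {
  asg <- data.frame(tf = c("T1", "T1", "T1", "T1", "T2"),
                    gene = c("g1", "g2", "g3", "g4", "g1"),
                    subtype = c("A", "A", "A", "B", "B"),
                    stringsAsFactors = FALSE)
  class(asg) <- c("signature_edges", "data.frame")
  p <- participation_scores(asg)
  expect_equal(p["T1", "A"], 0.75)
  expect_equal(p["T1", "B"], 0.25)
  expect_equal(p["T2", "B"], 1)
  expect_equal(unname(rowSums(p)), c(1, 1))
  # majority rule for signature-TF assignment
  tfa <- signature_tfs(p)
  expect_equal(tfa[["T1"]], "A")
  expect_equal(tfa[["T2"]], "B")
  # 50/50 split: no assignment
  asg2 <- asg[c(1, 4), ]
  expect_message(tfa2 <- signature_tfs(participation_scores(asg2)),
                 "no majority")
  expect_false("T1" %in% names(tfa2))
  # empty assignment gives an empty table
  expect_equal(nrow(participation_scores(asg[0, ])), 0)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  withr::with_seed(111, {
    universe <- sprintf("g%03d", 1:40)
    for (rep in 1:10) {
      sig <- sample(universe, sample(5:15, 1))
      reg <- sample(universe, sample(5:15, 1))
      asg <- data.frame(tf = "T1", gene = reg, subtype = "A",
                        stringsAsFactors = FALSE)
      res <- differential_regulation_enrichment(asg, list(A = sig), universe)
      q <- length(intersect(reg, sig))
      expect_equal(res$p,
                   oracle_hyper_upper(q, 40, length(sig), length(reg)),
                   tolerance = 1e-12)
    }
    # complete containment in a small universe
    asg3 <- data.frame(tf = "T1", gene = c("g001", "g002"), subtype = "A")
    res3 <- differential_regulation_enrichment(
      asg3, list(A = c("g001", "g002", "g003")), sprintf("g%03d", 1:6))
    expect_equal(res3$p, oracle_hyper_upper(2, 6, 3, 2), tolerance = 1e-12)
    # zero overlap where much is expected: p near 1
    asg4 <- data.frame(tf = "T1", gene = sprintf("g%03d", 21:40),
                       subtype = "A")
    res4 <- differential_regulation_enrichment(
      asg4, list(A = sprintf("g%03d", 1:20)), universe)
    expect_gt(res4$p, 0.999)
    expect_error(differential_regulation_enrichment(asg4, list(A = "g001"),
                                                    character(0)),
                 "empty")
  })
})

test_that("hypergeometric p-values are uniform under a random null", {
  withr::with_seed(112, {
    universe <- sprintf("g%04d", 1:2000)
    sims <- replicate(500, {
      sig <- sample(universe, 400)
      reg <- sample(universe, 300)
      asg <- data.frame(tf = "T1", gene = reg, subtype = "A",
                        stringsAsFactors = FALSE)
      c(p = differential_regulation_enrichment(asg, list(A = sig),
                                               universe)$p,
        q = length(intersect(reg, sig)))
    })
    # a discrete upper-tail p is a staircase; its randomized version
    # p - U * P(X = q) is exactly Uniform(0,1) iff p = P(X >= q) is correct
    pmf <- stats::dhyper(sims["q", ], 400, 1600, 300)
    ps_rand <- sims["p", ] - stats::runif(500) * pmf
    expect_gt(stats::ks.test(ps_rand, "punif")$p.value, 0.01)
    # the unjittered p stays valid (never anti-conservative) at alpha 0.05
    expect_lte(mean(sims["p", ] <= 0.05), 0.07)
  })
})

test_that("TF-target correlation shift detects a displaced group", {
  withr::with_seed(113, {
    # identical groups: p near 1
    truth <- generate_regulatory_truth(3, 20, "A", 0.4, 0, 0.2, seed = 114)
    expr <- simulate_cohort(truth, 40, seed = 115)
    bb <- candidate_network(truth$backbone$tf, truth$backbone$gene)
    targets <- sort(unique(bb$gene))
    half <- targets[seq(1, length(targets), by = 2)]
    res <- tf_target_correlation_shift(expr, bb, half)
    expect_gt(res$p_value, 0.01)  # arbitrary split: no systematic shift
    expect_equal(length(res$diff_reg) + length(res$background),
                 length(unique(bb$gene)))

    # power: shifted Gaussian groups are detected by the rank-sum test
    hits <- 0
    for (i in 1:200) {
      g1 <- rnorm(100, 0.3, 0.3)
      g2 <- rnorm(100, 0.0, 0.3)
      if (stats::wilcox.test(g1, g2, exact = FALSE)$p.value < 0.01)
        hits <- hits + 1
    }
    expect_gte(hits / 200, 0.95)

    # single-TF targets reduce to plain Pearson correlation
    n_regs <- table(bb$gene)
    single <- names(n_regs)[n_regs == 1][1]
    if (!is.na(single)) {
      tf1 <- bb$tf[bb$gene == single]
      all_r <- c(res$diff_reg, res$background)
      expect_equal(unname(all_r[single]),
                   stats::cor(expr$values[single, ], expr$values[tf1, ]))
    }
    expect_error(tf_target_correlation_shift(expr, bb, character(0)),
                 "non-empty")
  })
})
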