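# Independent oracles used across the suite. These deliberately re-derive
# results with naive algorithms (loops, enumeration, damped iteration) and
# never call the package internals they are checking.

# --- propagation oracle -----------------------------------------------------
# Knockdown propagation by explicit topological ordering on a DAG of TFs.
# Fold-change semantics: log2 new = log2 base + (sum new terms - sum base
# terms), term(x) = log2((1 + F x)/(1 + x)). Fails if the TF graph reachable
# from the seed is cyclic.
oracle_topo_perturb <- function(fvals, expr, seed_tf, kf) {
  vals <- if (inherits(expr, "expression_set")) expr$values else as.matrix(expr)
  ed <- fvals$edges
  tfs <- sort(unique(ed$tf))
  # reachable TFs via BFS on TF->TF edges
  tf_edges <- ed[ed$gene %in% tfs, , drop = FALSE]
  reach <- seed_tf
  repeat {
    nxt <- unique(tf_edges$gene[tf_edges$tf %in% reach])
    new <- setdiff(nxt, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  # naive topological order of reach (seed treated as source)
  remaining <- setdiff(reach, seed_tf)
  order <- character(0)
  done <- seed_tf
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(u) {
      regs <- tf_edges$tf[tf_edges$gene == u]
      length(setdiff(intersect(regs, reach), done)) == 0
    }, logical(1))]
    if (!length(ready)) stop("cycle: oracle requires a DAG")
    ready <- sort(ready)
    order <- c(order, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  cur <- vals
  cur[seed_tf, ] <- cur[seed_tf, ] * kf
  recompute <- function(gene) {
    ged <- ed[ed$gene == gene, , drop = FALSE]
    for (s in colnames(cur)) {
      f <- 2^ged$log2f
      xn <- cur[ged$tf, s]
      xb <- vals[ged$tf, s]
      delta <- sum(log2((1 + f * xn) / (1 + xn))) -
        sum(log2((1 + f * xb) / (1 + xb)))
      # zero predicted change leaves the value untouched (no log round-trip)
      if (delta != 0) cur[gene, s] <<- 2^(log2(cur[gene, s]) + delta)
    }
  }
  for (u in order) if (u %in% ed$gene) recompute(u)
  updated <- c(seed_tf, order)
  targets <- sort(setdiff(unique(ed$gene[ed$tf %in% updated]), tfs))
  for (g in intersect(targets, rownames(cur))) recompute(g)
  cur
}

# --- damped fixed-point solver for Exponential Ranking ----------------------
oracle_damped_ranking <- function(A, mu, p0, tol = 1e-10, max_iter = 50000L) {
  p <- p0 / sum(p0)
  step <- function(p) {
    v <- as.numeric(t(A) %*% p) / mu
    e <- exp(v - max(v))
    e / sum(e)
  }
  for (i in seq_len(max_iter)) {
    p_new <- 0.5 * p + 0.5 * step(p)
    if (sqrt(sum((p_new - p)^2)) < tol) return(p_new)
    p <- p_new
  }
  p
}

# --- exact enumeration of hypergeometric tails ------------------------------
# P(X >= q) for X ~ Hypergeometric(N, K, n), via explicit choose() sums.
oracle_hyper_upper <- function(q, N, K, n) {
  ks <- max(0, q):min(K, n)
  if (q > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table by enumeration: sum of
# probabilities of all tables with the same margins that are no more likely
# than the observed one (standard definition).
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; K <- a + cc; N <- a + b + cc + d; n <- m1
  prob <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  xs <- max(0, n - (N - K)):min(K, n)
  p_obs <- prob(a)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <=
                                     p_obs * (1 + 1e-7)])
}

# --- brute-force precision-recall AUC ---------------------------------------
oracle_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  precision <- recall <- numeric(length(thr))
  for (i in seq_along(thr)) {
    sel <- scores >= thr[i]
    precision[i] <- sum(labels & sel) / sum(sel)
    recall[i] <- sum(labels & sel) / sum(labels)
  }
  r <- c(0, recall); p <- c(precision[1], precision)
  sum(diff(r) * (p[-length(p)] + p[-1]) / 2)
}

# --- tiny fixture builders --------------------------------------------------
# A small fitted-style f_matrix built directly from an edge specification.
make_fvals <- function(tf, gene, log2f, basal_genes = NULL, basal = NULL) {
  genes <- unique(gene)
  if (is.null(basal_genes)) {
    basal_genes <- genes
    basal <- rep(10, length(genes))
  }
  f_matrix(data.frame(tf = tf, gene = gene, log2f = log2f,
                      stringsAsFactors = FALSE),
           stats::setNames(basal, basal_genes))
}

# Random positive expression matrix with named rows/columns.
make_expr_matrix <- function(genes, n_samples, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(2^stats::rnorm(length(genes) * n_samples, 3, 1),
                length(genes), n_samples,
                dimnames = list(genes, sprintf("s%03d", seq_len(n_samples))))
    m
  })
}

# Random DAG f_matrix over n_tf TFs and n_gene extra genes; TF i can only
# regulate TFs with larger index (guarantees acyclicity).
make_random_dag_fvals <- function(n_tf, n_gene, p_edge = 0.4, seed = 1L) {
  withr::with_seed(seed, {
    tfs <- sprintf("T%02d", seq_len(n_tf))
    genes <- sprintf("g%02d", seq_len(n_gene))
    ed <- NULL
    for (i in seq_len(n_tf)) {
      for (j in seq_len(n_tf)) {
        if (j > i && stats::runif(1) < p_edge)
          ed <- rbind(ed, data.frame(tf = tfs[i], gene = tfs[j]))
      }
      for (g in genes) if (stats::runif(1) < p_edge)
        ed <- rbind(ed, data.frame(tf = tfs[i], gene = g))
    }
    if (is.null(ed)) ed <- data.frame(tf = tfs[1], gene = genes[1])
    ed$log2f <- stats::runif(nrow(ed), -2, 2)
    targets <- unique(ed$gene)
    f_matrix(ed, stats::setNames(2^stats::runif(length(targets), 2, 4),
                                 targets))
  })
}

# Random (possibly cyclic) f_matrix: arbitrary TF->TF edges allowed.
make_random_cyclic_fvals <- function(n_tf, n_gene, p_edge = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    tfs <- sprintf("T%02d", seq_len(n_tf))
    genes <- sprintf("g%02d", seq_len(n_gene))
    nodes <- c(tfs, genes)
    ed <- NULL
    for (i in tfs) for (j in nodes) {
      if (i != j && stats::runif(1) < p_edge)
        ed <- rbind(ed, data.frame(tf = i, gene = j))
    }
    if (is.null(ed)) ed <- data.frame(tf = tfs[1], gene = genes[1])
    ed$log2f <- stats::runif(nrow(ed), -2, 2)
    targets <- unique(ed$gene)
    f_matrix(ed, stats::setNames(2^stats::runif(length(targets), 2, 4),
                                 targets))
  })
}
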