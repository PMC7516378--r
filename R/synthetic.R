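# Synthetic ground-truth generators
#
# These generators produce regulatory systems with the statistical structure
# the pipeline assumes: a sparse TF->gene backbone, per-subtype regulatory
# capacities (F values) with a planted fraction of subtype-unique "signature"
# edges, lognormal TF expression, multiplicative (log2-additive Gaussian)
# noise, small signed protein networks, and essentiality scores that are
# sparse linear functions of protein-activity deltas.

#' Generate a ground-truth regulatory system
#'
#' Draws a TF-to-gene backbone at a given density and assigns each edge a
#' regulatory capacity per subtype. Baseline log2 F is sampled uniformly on
#' \[-2.5, 2.5\] excluding (-0.1, 0.1) so every edge is identifiable but not
#' extreme. A fraction `frac_signature_edges` of edges is made
#' subtype-specific: in one randomly chosen subtype the edge's log2 F is
#' redrawn with flipped sign and magnitude uniform on \[1.5, 2.5\], emulating
#' TF repurposing (the same TF switching regulatory direction between
#' subtypes). Signature edges are planted on distinct target genes so that
#' each planted effect is identifiable (two repurposed regulators on one
#' gene confound each other's fitted capacity); when the requested fraction
#' exceeds the number of available genes the count is capped with a
#' warning. All remaining edges share F across subtypes.
#'
#' @param n_tfs,n_genes Counts of regulators and target genes.
#' @param subtypes Character vector of subtype labels (at least one).
#' @param edge_density Fraction of the complete TF-by-gene bipartite graph to
#'   include; exactly `round(edge_density * n_tfs * n_genes)` edges are drawn
#'   without replacement.
#' @param frac_signature_edges Fraction of edges planted as subtype-unique.
#' @param noise_sd SD of additive Gaussian noise in log2 space used by
#'   [simulate_expression].
#' @param seed Integer seed; the result is bit-reproducible.
#' @return An object of class `ground_truth`: list with `backbone` (data
#'   frame tf, gene), `f` (data frame tf, gene, subtype, log2f), `basal`
#'   (named positive vector), `signature` (data frame of planted edges),
#'   `subtypes`, `noise_sd`, `seed`.
#' @export
generate_regulatory_truth <- function(n_tfs, n_genes, subtypes = "A",
                                      edge_density = 0.3,
                                      frac_signature_edges = 0,
                                      noise_sd = 0.1, seed = 1L) {
  if (edge_density <= 0 || edge_density > 1)
    stop("edge_density must be in (0, 1]")
  if (frac_signature_edges < 0 || frac_signature_edges > 1)
    stop("frac_signature_edges must be in [0, 1]")
  if (n_tfs < 1 || n_genes < 1) stop("need at least one TF and one gene")
  if (!length(subtypes)) stop("need at least one subtype")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  subtypes <- as.character(subtypes)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  genes <- sprintf("G%03d", seq_len(n_genes))
  withr::with_seed(as.integer(seed), {
    n_edges <- max(1L, round(edge_density * n_tfs * n_genes))
    idx <- sort(sample.int(n_tfs * n_genes, n_edges))
    backbone <- data.frame(
      tf = tfs[(idx - 1L) %/% n_genes + 1L],
      gene = genes[(idx - 1L) %% n_genes + 1L],
      stringsAsFactors = FALSE)
    base_l2f <- sample(c(-1, 1), n_edges, replace = TRUE) *
      stats::runif(n_edges, 0.1, 2.5)
    f <- do.call(rbind, lapply(subtypes, function(s)
      data.frame(tf = backbone$tf, gene = backbone$gene, subtype = s,
                 log2f = base_l2f, stringsAsFactors = FALSE)))
    n_sig <- round(frac_signature_edges * n_edges)
    signature <- data.frame(tf = character(0), gene = character(0),
                            subtype = character(0), log2f = numeric(0),
                            stringsAsFactors = FALSE)
    if (n_sig > 0) {
      # plant on distinct target genes: greedy pass over a shuffled edge list
      cand <- sample.int(n_edges)
      sig_idx <- integer(0); seen <- character(0)
      for (j in cand) {
        g <- backbone$gene[j]
        if (g %in% seen) next
        sig_idx <- c(sig_idx, j); seen <- c(seen, g)
        if (length(sig_idx) == n_sig) break
      }
      if (length(sig_idx) < n_sig) {
        warning("signature edges capped at one per target gene: ",
                length(sig_idx), " of ", n_sig, " requested")
        n_sig <- length(sig_idx)
      }
      sig_sub <- sample(subtypes, n_sig, replace = TRUE)
      new_val <- -sign(base_l2f[sig_idx]) * stats::runif(n_sig, 1.5, 2.5)
      for (i in seq_len(n_sig)) {
        row <- f$tf == backbone$tf[sig_idx[i]] &
          f$gene == backbone$gene[sig_idx[i]] & f$subtype == sig_sub[i]
        f$log2f[row] <- new_val[i]
      }
      signature <- data.frame(tf = backbone$tf[sig_idx],
                              gene = backbone$gene[sig_idx],
                              subtype = sig_sub, log2f = new_val,
                              stringsAsFactors = FALSE)
    }
    basal <- 2^stats::rnorm(n_genes, mean = 5, sd = 1)
    names(basal) <- genes
    structure(list(backbone = backbone, f = f, basal = basal,
                   signature = signature, subtypes = subtypes,
                   tfs = tfs, genes = genes,
                   noise_sd = noise_sd, seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d TFs -> %d genes, %d edges, %d subtype(s), %d signature edges\n",
              length(x$tfs), length(x$genes), nrow(x$backbone),
              length(x$subtypes), nrow(x$signature)))
  invisible(x)
}

# Ground-truth parameters of one subtype as an f_matrix.
#' Extract one subtype's ground-truth parameters as an [f_matrix]
#' @param truth A `ground_truth`.
#' @param subtype Subtype label (defaults to the first).
#' @return An [f_matrix] holding the true F values and basal levels.
#' @export
truth_f_matrix <- function(truth, subtype = truth$subtypes[1]) {
  ed <- truth$f[truth$f$subtype == subtype, c("tf", "gene", "log2f")]
  f_matrix(ed, truth$basal, subtype = subtype, lambda = 0)
}

#' Simulate expression from a ground truth by the forward model
#'
#' For each target gene and sample,
#' `log2 y = log2 basal + sum_j log2((1 + F_j x_j)/(1 + x_j)) + e`,
#' `e ~ N(0, noise_sd^2)`, using the F values of the sample's subtype. TF
#' rows carry the supplied expression unchanged; outputs are nonnegative
#' after back-transform by construction.
#'
#' @param truth A `ground_truth`.
#' @param tf_expression Nonnegative numeric matrix, TFs x samples.
#' @param sample_subtype Named character vector assigning every sample
#'   (column) a subtype from `truth$subtypes`.
#' @param seed Integer seed for the noise draw.
#' @return An [expression_set] with TF rows first, then target genes.
#' @export
simulate_expression <- function(truth, tf_expression, sample_subtype,
                                seed = truth$seed) {
  tf_expression <- as.matrix(tf_expression)
  if (any(tf_expression < 0)) stop("TF expression must be nonnegative")
  if (!all(truth$tfs %in% rownames(tf_expression)))
    stop("tf_expression must cover every TF in the truth")
  samples <- colnames(tf_expression)
  if (!all(samples %in% names(sample_subtype)))
    stop("sample_subtype must cover every sample")
  sample_subtype <- sample_subtype[samples]
  if (!all(sample_subtype %in% truth$subtypes))
    stop("unknown subtype label in sample_subtype")
  genes <- truth$genes
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  withr::with_seed(as.integer(seed), {
    for (s in truth$subtypes) {
      cols <- which(sample_subtype == s)
      if (!length(cols)) next
      fv <- truth_f_matrix(truth, s)
      pred <- predict_expression(fv, tf_expression[, cols, drop = FALSE])
      noise <- matrix(stats::rnorm(length(pred), 0, truth$noise_sd),
                      nrow(pred), ncol(pred))
      out[, cols] <- 2^(log2(pred) + noise)
    }
  })
  expression_set(rbind(tf_expression[truth$tfs, , drop = FALSE], out),
                 subtype = sample_subtype)
}

#' Simulate a full subtype-labelled cohort
#'
#' Samples TF expression i.i.d. lognormal (log2 mean 0, log2 SD 1) — TFs are
#' treated as exogenous inputs — then pushes it through
#' [simulate_expression].
#'
#' @param truth A `ground_truth`.
#' @param samples_per_subtype Number of samples per subtype.
#' @param seed Integer seed.
#' @return An [expression_set] with subtype labels attached.
#' @export
simulate_cohort <- function(truth, samples_per_subtype, seed = truth$seed) {
  n <- samples_per_subtype * length(truth$subtypes)
  samples <- sprintf("S%04d", seq_len(n))
  sample_subtype <- rep(truth$subtypes, each = samples_per_subtype)
  names(sample_subtype) <- samples
  tf_expr <- withr::with_seed(as.integer(seed),
    matrix(2^stats::rnorm(length(truth$tfs) * n, 0, 1),
           length(truth$tfs), n, dimnames = list(truth$tfs, samples)))
  simulate_expression(truth, tf_expr, sample_subtype,
                      seed = as.integer(seed) + 1L)
}

#' Generate a random signed, directed protein network
#'
#' Simple directed graph with `n_edges` edges sampled uniformly without
#' replacement from all ordered pairs; each edge gets sign -1 with
#' probability `frac_inhibitory` and a likelihood weight uniform on (0, 1].
#'
#' @param n_proteins,n_edges Node and edge counts
#'   (`n_edges <= n_proteins * (n_proteins - 1)`).
#' @param frac_inhibitory Probability of an inhibitory edge.
#' @param seed Integer seed.
#' @return A [signed_network].
#' @export
generate_signed_protein_network <- function(n_proteins, n_edges,
                                            frac_inhibitory = 0.3,
                                            seed = 1L) {
  max_edges <- n_proteins * (n_proteins - 1)
  if (n_edges > max_edges) stop("n_edges exceeds the number of ordered pairs")
  if (n_edges < 1) stop("need at least one edge")
  if (frac_inhibitory < 0 || frac_inhibitory > 1)
    stop("frac_inhibitory must be in [0, 1]")
  prots <- sprintf("P%03d", seq_len(n_proteins))
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(max_edges, n_edges)
    src_i <- (idx - 1L) %/% (n_proteins - 1L) + 1L
    off <- (idx - 1L) %% (n_proteins - 1L) + 1L
    dst_i <- ifelse(off >= src_i, off + 1L, off)
    sign <- ifelse(stats::runif(n_edges) < frac_inhibitory, -1, 1)
    weight <- 1 - stats::runif(n_edges)  # uniform on (0, 1]
    signed_network(data.frame(src = prots[src_i], dst = prots[dst_i],
                              sign = sign, weight = weight,
                              stringsAsFactors = FALSE),
                   proteins = prots)
  })
}

#' Simulate essentiality scores from activity deltas
#'
#' Generative twin of the essentiality regression: for each TF a random
#' sparse support of `n_true_predictors` proteins is chosen, coefficients
#' are `+-coef_scale` with random sign, and the essentiality score of each
#' cell line is the linear combination of that TF's activity deltas plus
#' Gaussian noise. The true support and coefficients are recorded for
#' recovery tests.
#'
#' Support proteins are drawn from those that actually respond to the TF's
#' perturbation (delta SD across cell lines at or above the
#' `min_signal_quantile` quantile): a dependency can only be mediated by
#' proteins whose activity the TF modulates, and a predictor whose signal
#' is below the noise floor would be unidentifiable by construction.
#' Chosen supports additionally satisfy design-incoherence constraints:
#' pairwise |correlation| of the support columns at most `max_support_cor`,
#' and preference for proteins without a near-duplicate column anywhere in
#' the design (|correlation| above `max_global_cor`). Planting a mediator
#' that is statistically indistinguishable from another protein makes
#' support recovery impossible for any regression method, so such
#' configurations are excluded from the generative model rather than from
#' the evaluation.
#'
#' @param activity_deltas Named list, one entry per TF, each a numeric
#'   matrix of cell lines x proteins (identical protein columns across TFs).
#' @param n_true_predictors Size of the true support per TF.
#' @param coef_scale Coefficient magnitude.
#' @param noise_sd SD of additive Gaussian noise on the scores.
#' @param seed Integer seed.
#' @param min_signal_quantile Quantile of the per-protein delta SD below
#'   which proteins are excluded from the true support (default 0.5; the
#'   eligible set is widened if it falls short of `n_true_predictors`).
#' @return List with `scores` (TF x cell-line matrix), `support` (named list
#'   of protein ids) and `coefficients` (named list of named vectors).
#' @export
simulate_essentiality <- function(activity_deltas, n_true_predictors,
                                  coef_scale = 1, noise_sd = 0.1, seed = 1L,
                                  min_signal_quantile = 0.7,
                                  max_support_cor = 0.7,
                                  max_global_cor = 0.9) {
  tfs <- names(activity_deltas)
  if (is.null(tfs)) stop("activity_deltas must be a named list (per TF)")
  prots <- colnames(activity_deltas[[1]])
  for (m in activity_deltas)
    if (!identical(colnames(m), prots))
      stop("activity_deltas must share identical protein columns")
  if (n_true_predictors > length(prots))
    stop("n_true_predictors exceeds the protein count")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  withr::with_seed(as.integer(seed), {
    lines <- rownames(activity_deltas[[1]])
    scores <- matrix(NA_real_, length(tfs), length(lines),
                     dimnames = list(tfs, lines))
    support <- stats::setNames(vector("list", length(tfs)), tfs)
    coefs <- stats::setNames(vector("list", length(tfs)), tfs)
    for (tf in tfs) {
      m <- activity_deltas[[tf]]
      sds <- apply(m, 2, stats::sd)
      eligible <- prots[sds >= stats::quantile(sds, min_signal_quantile) &
                          sds > 0]
      if (length(eligible) < n_true_predictors)
        eligible <- prots[order(sds, decreasing = TRUE)][
          seq_len(n_true_predictors)]
      pool <- eligible
      if (length(eligible) && nrow(m) > 2 && all(sds[eligible] > 0)) {
        # prefer proteins without a near-duplicate column anywhere
        cm <- abs(stats::cor(m[, eligible, drop = FALSE], m))
        for (i in seq_along(eligible))
          cm[i, eligible[i]] <- 0
        glob <- eligible[apply(cm, 1, max) <= max_global_cor]
        if (length(glob) >= n_true_predictors) pool <- glob
      }
      # greedy incoherent support: visit candidates in random order, skip
      # any too correlated with the support chosen so far
      cand <- sample(pool)
      sup <- character(0)
      if (any(sds[pool] > 0) && nrow(m) > 2) {
        for (p in cand) {
          if (length(sup) == n_true_predictors) break
          if (length(sup) &&
              max(abs(stats::cor(m[, p], m[, sup, drop = FALSE]))) >
                max_support_cor) next
          sup <- c(sup, p)
        }
      }
      if (length(sup) < n_true_predictors)
        sup <- c(sup, setdiff(sample(eligible), sup)[
          seq_len(n_true_predictors - length(sup))])
      beta <- coef_scale * sample(c(-1, 1), n_true_predictors, replace = TRUE)
      names(beta) <- sup
      scores[tf, ] <- as.numeric(activity_deltas[[tf]][, sup, drop = FALSE] %*% beta) +
        stats::rnorm(length(lines), 0, noise_sd)
      support[[tf]] <- sup
      coefs[[tf]] <- beta
    }
    list(scores = scores, support = support, coefficients = coefs)
  })
}
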