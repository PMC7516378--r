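# Subtype-specific (repurposed) regulatory signatures
#
# An edge is subtype-specific when its fitted log2 F deviates from a
# label-permutation null by many standard deviations: shuffling subtype
# labels while preserving group sizes destroys subtype structure but keeps
# everything else (sample sizes, expression marginals, optimizer behavior)
# intact, making the permuted fits an exact null for subtype specificity.

#' Permutation null for subtype-specific F values
#'
#' Shuffles subtype labels `n_shuffles` times (preserving group sizes),
#' refits the model per shuffled subtype, and accumulates the per-edge,
#' per-subtype mean and SD of log2 F across shuffles. A shuffle whose fit
#' fails is dropped with a warning and the shuffle count adjusted.
#'
#' @param backbone A [candidate_network].
#' @param expr An [expression_set] with subtype labels.
#' @param n_shuffles Number of label shuffles (reference analysis uses 30;
#'   at least 2).
#' @param seed Integer seed (one derived seed per shuffle).
#' @param config A [fit_config] used for every refit.
#' @return Object of class `permutation_null`: data frame `stats` with
#'   columns `tf`, `gene`, `subtype`, `null_mean`, `null_sd`, plus
#'   `n_shuffles`.
#' @export
permute_and_refit <- function(backbone, expr, n_shuffles = 30L, seed = 1L,
                              config = fit_config()) {
  if (n_shuffles < 2) stop("need at least 2 shuffles")
  if (is.null(expr$subtype)) stop("expression has no subtype labels")
  vals <- expr_values(expr)
  subtypes <- sort(unique(expr$subtype))
  acc <- NULL  # matrix of log2f draws: rows = edge x subtype, cols = shuffles
  key <- NULL
  kept <- 0L
  for (s in seq_len(n_shuffles)) {
    labs <- withr::with_seed(as.integer(seed) + s, sample(expr$subtype))
    names(labs) <- colnames(vals)
    shuffled <- expression_set(vals, subtype = labs)
    draw <- tryCatch({
      res <- lapply(subtypes, function(st)
        fit_subtype_model(backbone, shuffled, st, config)$fvals$edges)
      do.call(rbind, Map(function(ed, st)
        data.frame(tf = ed$tf, gene = ed$gene, subtype = st,
                   log2f = ed$log2f, stringsAsFactors = FALSE),
        res, subtypes))
    }, error = function(e) {
      warning("shuffle ", s, " dropped: ", conditionMessage(e))
      NULL
    })
    if (is.null(draw)) next
    kept <- kept + 1L
    if (is.null(acc)) {
      key <- paste(draw$tf, draw$gene, draw$subtype, sep = "\r")
      acc <- matrix(NA_real_, length(key), n_shuffles,
                    dimnames = list(key, NULL))
    }
    acc[paste(draw$tf, draw$gene, draw$subtype, sep = "\r"), kept] <- draw$log2f
  }
  if (kept < 2) stop("fewer than 2 successful shuffles")
  acc <- acc[, seq_len(kept), drop = FALSE]
  parts <- do.call(rbind, strsplit(rownames(acc), "\r", fixed = TRUE))
  stats_df <- data.frame(tf = parts[, 1], gene = parts[, 2],
                         subtype = parts[, 3],
                         null_mean = rowMeans(acc),
                         null_sd = apply(acc, 1, stats::sd),
                         stringsAsFactors = FALSE)
  structure(list(stats = stats_df, n_shuffles = kept),
            class = "permutation_null")
}

#' Call subtype-specific signature edges
#'
#' Flags edge (tf, gene) in subtype s when the unshuffled log2 F deviates
#' from the permutation-null mean by at least `sd_threshold` null SDs:
#' `|log2F - null_mean| / max(null_sd, sd_floor) >= sd_threshold`. The SD
#' floor guards against degenerate zero-SD nulls; an edge whose unshuffled
#' value equals a zero-SD null mean is never flagged.
#'
#' @param fvals_by_subtype Named list of [f_matrix] objects (unshuffled
#'   fits), one per subtype.
#' @param null A `permutation_null` covering all edges.
#' @param sd_threshold Deviation threshold in null SD units (reference uses
#'   5); the boundary is inclusive.
#' @param sd_floor Lower bound applied to the null SD before division.
#' @return Data frame of class `signature_edges` with columns `tf`, `gene`,
#'   `subtype`, `log2f`, `z`.
#' @export
call_signature_edges <- function(fvals_by_subtype, null, sd_threshold = 5,
                                 sd_floor = 1e-6) {
  obs <- do.call(rbind, lapply(names(fvals_by_subtype), function(st) {
    ed <- fvals_by_subtype[[st]]$edges
    data.frame(tf = ed$tf, gene = ed$gene, subtype = st, log2f = ed$log2f,
               stringsAsFactors = FALSE)
  }))
  key <- function(d) paste(d$tf, d$gene, d$subtype, sep = "\r")
  ns <- null$stats
  idx <- match(key(obs), key(ns))
  if (anyNA(idx)) stop("permutation null does not cover all edges")
  z <- abs(obs$log2f - ns$null_mean[idx]) / pmax(ns$null_sd[idx], sd_floor)
  out <- obs[z >= sd_threshold, , drop = FALSE]
  out$z <- z[z >= sd_threshold]
  rownames(out) <- NULL
  class(out) <- c("signature_edges", "data.frame")
  out
}

#' Participation scores of TFs across subtype signatures
#'
#' For each TF with at least one signature edge, the row gives the fraction
#' of its signature edges falling in each subtype:
#' `|signature edges of tf in s| / |signature edges of tf in any subtype|`.
#' With disjoint per-subtype signature sets rows sum to exactly 1.
#'
#' @param assignment A `signature_edges` data frame (from
#'   [call_signature_edges]).
#' @param subtypes Optional subtype labels fixing the column order.
#' @return TF x subtype matrix of fractions (TFs without signature edges are
#'   omitted); empty assignment gives a 0-row matrix.
#' @export
participation_scores <- function(assignment,
                                 subtypes = sort(unique(assignment$subtype))) {
  if (!nrow(assignment))
    return(matrix(numeric(0), 0, length(subtypes),
                  dimnames = list(NULL, subtypes)))
  tfs <- sort(unique(assignment$tf))
  counts <- table(factor(assignment$tf, tfs),
                  factor(assignment$subtype, subtypes))
  m <- matrix(as.numeric(counts), length(tfs), length(subtypes),
              dimnames = list(tfs, subtypes))
  m / rowSums(m)
}

#' Assign each TF its signature subtype
#'
#' A TF's signature subtype is the arg-max of its participation row,
#' required to exceed 0.5 (a majority of its signature edges); ties or
#' sub-majority maxima yield no assignment (dropped, with a message).
#'
#' @param participation TF x subtype matrix from [participation_scores].
#' @return Named character vector tf -> subtype.
#' @export
signature_tfs <- function(participation) {
  out <- character(0)
  for (tf in rownames(participation)) {
    row <- participation[tf, ]
    best <- which(row == max(row))
    if (length(best) == 1 && row[best] > 0.5)
      out[tf] <- colnames(participation)[best]
  }
  dropped <- setdiff(rownames(participation), names(out))
  if (length(dropped))
    message("no majority subtype for: ", paste(dropped, collapse = ", "))
  out
}

#' Enrichment of differentially regulated genes in expression signatures
#'
#' Per subtype, an upper-tail hypergeometric test for the overlap between
#' genes carrying at least one signature edge in that subtype and the
#' subtype's expression-signature gene set, over a stated gene universe.
#'
#' @param assignment A `signature_edges` data frame.
#' @param expression_signature_genes Named list: subtype -> character vector
#'   of signature genes (subsets of `universe`).
#' @param universe Character vector of all genes considered.
#' @return Data frame with columns `subtype`, `n_regulated`, `n_signature`,
#'   `overlap`, `fold`, `p`.
#' @export
differential_regulation_enrichment <- function(assignment,
                                               expression_signature_genes,
                                               universe) {
  if (!length(universe)) stop("universe is empty")
  subs <- names(expression_signature_genes)
  out <- lapply(subs, function(s) {
    sig <- intersect(expression_signature_genes[[s]], universe)
    reg <- intersect(unique(assignment$gene[assignment$subtype == s]), universe)
    q <- length(intersect(reg, sig))
    N <- length(universe); K <- length(sig); n <- length(reg)
    p <- stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n == 0 || K == 0) NA_real_ else (q / n) / (K / N)
    data.frame(subtype = s, n_regulated = n, n_signature = K, overlap = q,
               fold = fold, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Shift in TF-target expression correlation between gene groups
#'
#' For every target gene the mean Pearson correlation between its expression
#' and that of its regulator TFs is computed; the distribution for
#' differentially regulated genes is compared to the remaining genes with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test. Genes without regulators
#' or without expression are skipped.
#'
#' @param expr An [expression_set].
#' @param backbone A [candidate_network].
#' @param differentially_regulated Character vector of target genes forming
#'   the first group; the second group is all other targets.
#' @return List with `diff_reg` and `background` numeric vectors of mean
#'   correlations and `p_value`.
#' @export
tf_target_correlation_shift <- function(expr, backbone,
                                        differentially_regulated) {
  vals <- expr_values(expr)
  net <- backbone[backbone$tf %in% rownames(vals) &
                    backbone$gene %in% rownames(vals), , drop = FALSE]
  by_gene <- split(net$tf, net$gene)
  mean_r <- vapply(names(by_gene), function(g) {
    tfs <- by_gene[[g]]
    mean(vapply(tfs, function(tf) stats::cor(vals[g, ], vals[tf, ]),
                numeric(1)))
  }, numeric(1))
  mean_r <- mean_r[is.finite(mean_r)]
  g1 <- mean_r[names(mean_r) %in% differentially_regulated]
  g2 <- mean_r[!(names(mean_r) %in% differentially_regulated)]
  if (!length(g1) || !length(g2)) stop("both gene groups must be non-empty")
  p <- stats::wilcox.test(g1, g2, exact = FALSE)$p.value
  list(diff_reg = g1, background = g2, p_value = p)
}
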