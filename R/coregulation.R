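# TF-TF co-regulation from F-value profiles
#
# Two TFs that act as functional partners tend to show correlated
# regulatory profiles (log2 F across shared targets), because per-gene fits
# distribute regulatory effect among co-bound regulators. Correlation is
# computed robustly: targets not regulated by both TFs are removed to avoid
# zero inflation, and a seeded consensus (RANSAC-style) line fit flags gross
# outliers before the Pearson coefficient is taken.

#' Robust (consensus) correlation of two regulatory profiles
#'
#' Restricts to targets regulated by both TFs (|log2 F| > `reg_threshold`
#' for each), fits a consensus line by seeded 2-point sampling with a MAD
#' residual threshold taken from an initial least-squares fit, grows the
#' inlier set to at least `min_inlier_fraction` of the points (smallest
#' residuals first), and returns the Pearson correlation of the inliers.
#' Returns exactly 0 whenever the usable inlier count is not greater than 3
#' or the inputs are degenerate (constant).
#'
#' @param f_a,f_b Named numeric vectors of log2 F indexed by target gene.
#' @param min_inlier_fraction Minimum fraction of points kept as inliers
#'   (default 0.8, i.e. at most 20% may be discarded as outliers).
#' @param seed Integer seed for the consensus sampling.
#' @param reg_threshold |log2 F| above which a target counts as regulated.
#' @param n_trials Number of 2-point consensus trials.
#' @return Scalar correlation in \[-1, 1\] (0 when undefined).
#' @export
ransac_correlation <- function(f_a, f_b, min_inlier_fraction = 0.8,
                               seed = 1L, reg_threshold = 0.1,
                               n_trials = 100L) {
  shared <- intersect(names(f_a), names(f_b))
  shared <- shared[abs(f_a[shared]) > reg_threshold &
                     abs(f_b[shared]) > reg_threshold]
  x <- as.numeric(f_a[shared]); y <- as.numeric(f_b[shared])
  n <- length(x)
  if (n <= 3) return(0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  inliers <- consensus_inliers(x, y, min_inlier_fraction, seed, n_trials)
  if (sum(inliers) <= 3) return(0)
  xi <- x[inliers]; yi <- y[inliers]
  if (stats::sd(xi) == 0 || stats::sd(yi) == 0) return(0)
  stats::cor(xi, yi)
}

# Seeded consensus line fit; returns a logical inlier mask of length(x).
consensus_inliers <- function(x, y, min_inlier_fraction, seed, n_trials) {
  n <- length(x)
  init <- stats::lm.fit(cbind(1, x), y)
  thr <- stats::mad(init$residuals)
  if (thr == 0) return(rep(TRUE, n))
  best_count <- -1L; best_resid <- NULL
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(n_trials)) {
      ij <- sample.int(n, 2L)
      dx <- x[ij[2]] - x[ij[1]]
      if (dx == 0) next
      slope <- (y[ij[2]] - y[ij[1]]) / dx
      icpt <- y[ij[1]] - slope * x[ij[1]]
      resid <- abs(y - (icpt + slope * x))
      count <- sum(resid <= thr)
      if (count > best_count) {
        best_count <- count
        best_resid <- resid
      }
    }
  })
  if (is.null(best_resid)) best_resid <- abs(init$residuals)
  inliers <- best_resid <= thr
  floor_n <- ceiling(min_inlier_fraction * n)
  if (sum(inliers) < floor_n) {
    ord <- order(best_resid)
    inliers <- rep(FALSE, n)
    inliers[ord[seq_len(floor_n)]] <- TRUE
  }
  inliers
}

#' All-pairs co-regulation matrix
#'
#' Applies [ransac_correlation] to the log2 F profiles of every unordered
#' TF pair of a fitted model. The result is symmetric; `n_shared` records
#' how many targets (regulated by both) entered each comparison, and r is 0
#' wherever `n_shared <= 3`.
#'
#' @param fvals An [f_matrix].
#' @param min_inlier_fraction,seed,reg_threshold,n_trials Passed to
#'   [ransac_correlation]; each pair gets a distinct seed derived from
#'   `seed`.
#' @return List of class `correlation_matrix` with symmetric matrices `r`
#'   and `n_shared` (TF x TF).
#' @export
all_pairs_coregulation <- function(fvals, min_inlier_fraction = 0.8,
                                   seed = 1L, reg_threshold = 0.1,
                                   n_trials = 100L) {
  tfs <- f_tfs(fvals)
  if (length(tfs) < 2) stop("need at least two TFs")
  profiles <- lapply(tfs, function(tf) {
    ed <- fvals$edges[fvals$edges$tf == tf, ]
    stats::setNames(ed$log2f, ed$gene)
  })
  names(profiles) <- tfs
  m <- length(tfs)
  r <- matrix(0, m, m, dimnames = list(tfs, tfs))
  ns <- matrix(0L, m, m, dimnames = list(tfs, tfs))
  pair_id <- 0L
  for (i in seq_len(m)) {
    for (j in i:m) {
      pair_id <- pair_id + 1L
      pa <- profiles[[i]]; pb <- profiles[[j]]
      shared <- intersect(names(pa), names(pb))
      shared <- shared[abs(pa[shared]) > reg_threshold &
                         abs(pb[shared]) > reg_threshold]
      ns[i, j] <- ns[j, i] <- length(shared)
      rij <- ransac_correlation(pa, pb, min_inlier_fraction,
                                seed = as.integer(seed) + pair_id,
                                reg_threshold = reg_threshold,
                                n_trials = n_trials)
      r[i, j] <- r[j, i] <- rij
    }
  }
  structure(list(r = r, n_shared = ns), class = "correlation_matrix")
}

#' Known-interaction reference
#'
#' @param a,b Character vectors of TF ids (unordered pairs; self-pairs are
#'   rejected).
#' @return Object of class `interaction_reference` holding canonical
#'   (sorted) pair keys.
#' @export
interaction_reference <- function(a, b) {
  if (any(a == b)) stop("self-pairs are not allowed in the reference")
  keys <- unique(pair_key(a, b))
  structure(list(pairs = keys), class = "interaction_reference")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a two-column TSV of known interacting pairs
#' @param path File path (no header; BIOGRID-style two-column exports work).
#' @return An [interaction_reference].
#' @export
read_interaction_reference <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  interaction_reference(as.character(df[[1]]), as.character(df[[2]]))
}

# Upper-triangle pairs of a correlation matrix that are defined
# (n_shared > 3), as a data.frame(a, b, r, key).
defined_pairs <- function(corr) {
  tfs <- rownames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  out <- data.frame(a = tfs[idx[, 1]], b = tfs[idx[, 2]],
                    r = corr$r[idx], n_shared = corr$n_shared[idx],
                    stringsAsFactors = FALSE)
  out <- out[out$n_shared > 3, , drop = FALSE]
  out$key <- pair_key(out$a, out$b)
  out
}

#' Enrichment of known interactions among top-correlated pairs
#'
#' Ranks defined pairs (n_shared > 3) by |r|, takes the top fraction, and
#' tests the 2x2 table (top vs rest) x (in reference vs not) with Fisher's
#' exact test. The odds ratio is the sample cross-product ratio ad/bc (Inf
#' when bc = 0 with ad > 0; NA when both are 0).
#'
#' @param corr A `correlation_matrix` from [all_pairs_coregulation].
#' @param reference An [interaction_reference] (non-empty).
#' @param top_fraction Fraction of pairs taken as "top" (reference analysis
#'   uses 0.01).
#' @return List with `odds_ratio`, `p_value`, `table` (2x2 matrix).
#' @export
interaction_enrichment <- function(corr, reference, top_fraction = 0.01) {
  if (!length(reference$pairs)) stop("reference is empty")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  pairs <- defined_pairs(corr)
  if (!nrow(pairs)) stop("no defined pairs to test")
  k <- ceiling(top_fraction * nrow(pairs))
  ord <- order(-abs(pairs$r), pairs$key)
  top <- logical(nrow(pairs)); top[ord[seq_len(k)]] <- TRUE
  pos <- pairs$key %in% reference$pairs
  tab <- matrix(c(sum(top & pos), sum(top & !pos),
                  sum(!top & pos), sum(!top & !pos)),
                2, 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("in_ref", "not_in_ref")))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * cc)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Precision-recall AUC for recovery of known interactions
#'
#' Ranks defined pairs by |r| descending and integrates precision over
#' recall by the trapezoid rule across unique score thresholds.
#'
#' @param corr A `correlation_matrix`.
#' @param reference An [interaction_reference]; at least one reference pair
#'   must be among the scored pairs.
#' @return Scalar AUC in \[0, 1\].
#' @export
interaction_pr_auc <- function(corr, reference) {
  pairs <- defined_pairs(corr)
  labels <- pairs$key %in% reference$pairs
  if (!any(labels)) stop("no positive pair among the scored pairs")
  pr_auc(abs(pairs$r), labels)
}

# Trapezoid PR-AUC over unique thresholds; scores higher = more confident.
pr_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  npos <- sum(labels)
  tp <- cumsum(labels)
  pred_pos <- seq_along(labels)
  last <- !duplicated(scores, fromLast = TRUE)  # last index of each threshold
  precision <- tp[last] / pred_pos[last]
  recall <- tp[last] / npos
  recall <- c(0, recall); precision <- c(precision[1], precision)
  sum(diff(recall) * (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
}
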