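# Cohort tools: centroid subtype classification, batch correction,
# standardization. These let external cohorts or cell lines be pushed
# through models fitted on a reference cohort.

#' Subtype centroids
#'
#' @param centers Numeric matrix, signature genes in rows (rownames), one
#'   column per subtype (colnames); at least two subtypes.
#' @return An object of class `centroids`.
#' @export
centroids <- function(centers) {
  centers <- as.matrix(centers)
  if (is.null(rownames(centers)) || is.null(colnames(centers)))
    stop("centroid matrix needs gene rownames and subtype colnames")
  if (ncol(centers) < 2) stop("need at least two subtype centroids")
  structure(list(signature_genes = rownames(centers), centers = centers),
            class = "centroids")
}

#' Read a centroid table (TSV: first column gene, one column per subtype)
#' @param path File path (header row of subtype names).
#' @return A [centroids] object.
#' @export
read_centroids <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  centroids(as.matrix(df))
}

#' Nearest-centroid subtype classification
#'
#' Each sample is assigned the subtype whose centroid has the highest
#' Pearson correlation with the sample's signature-gene expression vector.
#' Pearson distance makes the call invariant to per-sample affine rescaling.
#' Ties are broken by lexicographic subtype label with a warning.
#'
#' @param expr An [expression_set] or matrix.
#' @param cents A [centroids] object. At least 50% of its signature genes
#'   must be present in `expr`, else an error lists the missing genes.
#' @return Named character vector: sample -> subtype.
#' @export
nearest_centroid_classify <- function(expr, cents) {
  vals <- expr_values(expr)
  sig <- cents$signature_genes
  present <- intersect(sig, rownames(vals))
  if (length(present) < 0.5 * length(sig))
    stop("fewer than 50% of signature genes present; missing: ",
         paste(utils::head(setdiff(sig, rownames(vals)), 20), collapse = ", "))
  m <- vals[present, , drop = FALSE]
  cen <- cents$centers[present, , drop = FALSE]
  r <- stats::cor(m, cen)  # samples x subtypes
  labs <- colnames(cen)[order(colnames(cen))]
  r <- r[, labs, drop = FALSE]
  out <- character(ncol(m)); names(out) <- colnames(m)
  tied <- FALSE
  for (i in seq_len(nrow(r))) {
    best <- which(r[i, ] == max(r[i, ]))
    if (length(best) > 1) tied <- TRUE
    out[i] <- labs[best[1]]  # labs already lexicographic
  }
  if (tied) warning("correlation ties broken by lexicographic subtype label")
  out
}

#' Remove linear batch effects
#'
#' Location-only adjustment in log2 space: per gene, the batch-mean offsets
#' (batch mean minus grand mean) are subtracted so all batch means coincide
#' at the per-gene grand mean, which is preserved exactly; values are then
#' back-transformed to the linear scale. A linear-model approximation to
#' covariate-aware batch tools, adequate when no design covariates are
#' modeled.
#'
#' @param expr An [expression_set] with strictly positive values (zeros are
#'   replaced by 1 with a warning before log2).
#' @param batch Named character vector sample -> batch tag; at least two
#'   batches with at least two samples each.
#' @return An [expression_set] on the linear scale.
#' @export
remove_batch_effects <- function(expr, batch = expr$batch) {
  vals <- expr_values(expr)
  if (is.null(batch)) stop("batch tags are required")
  if (!all(colnames(vals) %in% names(batch)))
    stop("batch tags must cover every sample")
  batch <- batch[colnames(vals)]
  tab <- table(batch)
  if (length(tab) < 2) stop("need at least two batches")
  if (any(tab < 2)) stop("every batch needs at least two samples")
  if (any(vals == 0)) {
    warning("zeros replaced by 1 before log2")
    vals[vals == 0] <- 1
  }
  lv <- log2(vals)
  grand <- rowMeans(lv)
  for (b in names(tab)) {
    cols <- which(batch == b)
    offset <- rowMeans(lv[, cols, drop = FALSE]) - grand
    lv[, cols] <- lv[, cols] - offset
  }
  expression_set(2^lv, subtype = expr$subtype, batch = batch)
}

#' Standardize expression per gene
#'
#' Per gene, centers to mean 0 and scales to SD 1 across samples. Intended
#' only as the input space for classification or embedding, never as
#' regression input (the regression requires nonnegative linear-scale
#' values), so a plain matrix is returned. Constant genes are dropped with a
#' warning.
#'
#' @param expr An [expression_set] or matrix.
#' @return Numeric matrix of z-scores (possibly fewer rows).
#' @export
standardize_expression <- function(expr) {
  vals <- expr_values(expr)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s) dropped", sum(sds == 0)))
    vals <- vals[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (vals - rowMeans(vals)) / sds
}
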