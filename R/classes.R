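#' Expression set container
#'
#' Light container for a nonnegative, linear-scale gene-by-sample expression
#' matrix with optional per-sample subtype and batch annotations. All model
#' fitting operates on linear-scale values; log2 transforms are internal.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames). Values must be nonnegative and finite.
#' @param subtype Optional named character vector mapping every sample
#'   (column) to a subtype label.
#' @param batch Optional named character vector mapping samples to batch tags.
#' @return An object of class `expression_set`: a list with elements
#'   `values`, `subtype`, `batch`.
#' @export
expression_set <- function(values, subtype = NULL, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression values need unique rownames (gene ids)")
  if (is.null(colnames(values)))
    stop("expression values need colnames (sample ids)")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and nonnegative")
  if (!is.null(subtype)) {
    if (!all(colnames(values) %in% names(subtype)))
      stop("subtype labels must cover every sample")
    subtype <- subtype[colnames(values)]
  }
  if (!is.null(batch)) {
    if (!all(colnames(values) %in% names(batch)))
      stop("batch tags must cover every sample")
    batch <- batch[colnames(values)]
  }
  structure(list(values = values, subtype = subtype, batch = batch),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$subtype)) {
    tab <- table(x$subtype)
    cat("  subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# Coerce an expression_set or plain matrix to a value matrix.
expr_values <- function(expr) {
  if (inherits(expr, "expression_set")) expr$values else as.matrix(expr)
}

# Subset samples of an expression_set, keeping annotations aligned.
expr_subset <- function(expr, samples) {
  expression_set(expr$values[, samples, drop = FALSE],
                 subtype = if (!is.null(expr$subtype)) expr$subtype[samples],
                 batch = if (!is.null(expr$batch)) expr$batch[samples])
}

#' Candidate regulatory network
#'
#' An unsigned directed TF-to-gene edge list with provenance tags, the
#' backbone over which regulatory-capacity (F) parameters are fitted.
#'
#' @param tf,gene Character vectors of equal length (edge endpoints).
#' @param provenance Character vector of source tags (recycled).
#' @return A `data.frame` with columns `tf`, `gene`, `provenance` and class
#'   `candidate_network`. Duplicate (tf, gene) pairs are merged, provenance
#'   concatenated.
#' @export
candidate_network <- function(tf = character(), gene = character(),
                              provenance = "unspecified") {
  df <- data.frame(tf = as.character(tf), gene = as.character(gene),
                   provenance = rep_len(as.character(provenance), length(tf)),
                   stringsAsFactors = FALSE)
  df <- dedupe_network(df)
  class(df) <- c("candidate_network", "data.frame")
  df
}

dedupe_network <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$tf, df$gene, sep = "\r")
  prov <- vapply(split(df$provenance, key), function(p)
    paste(sort(unique(unlist(strsplit(p, ";", fixed = TRUE)))), collapse = ";"),
    character(1))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$provenance <- prov[paste(out$tf, out$gene, sep = "\r")]
  out <- out[order(out$tf, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fitted F-value matrix for one subtype
#'
#' Holds the regulatory-capacity parameters of the thermodynamic model for a
#' single subtype: one positive F value per backbone edge (stored as log2 F)
#' and one positive basal expression level per target gene.
#'
#' @param edges Data frame with columns `tf`, `gene`, `log2f`.
#' @param basal Named numeric vector of positive basal levels per target gene.
#' @param subtype Subtype label the fit belongs to.
#' @param lambda Penalty strength used in the fit.
#' @param converged Optional named logical vector per gene.
#' @return An object of class `f_matrix`.
#' @export
f_matrix <- function(edges, basal, subtype = NA_character_, lambda = NA_real_,
                     converged = NULL) {
  stopifnot(all(c("tf", "gene", "log2f") %in% names(edges)))
  if (any(!is.finite(edges$log2f))) stop("log2f values must be finite")
  if (any(basal <= 0)) stop("basal levels must be positive")
  structure(list(edges = as.data.frame(edges)[, c("tf", "gene", "log2f")],
                 basal = basal, subtype = subtype, lambda = lambda,
                 converged = converged),
            class = "f_matrix")
}

#' @export
print.f_matrix <- function(x, ...) {
  cat(sprintf("<f_matrix> subtype=%s: %d edges, %d target genes, lambda=%s\n",
              x$subtype, nrow(x$edges), length(x$basal),
              format(x$lambda)))
  invisible(x)
}

# TF universe of an f_matrix: every id that acts as a regulator.
f_tfs <- function(fvals) sort(unique(fvals$edges$tf))

# Regulator table split by target gene (list of data.frames).
f_by_gene <- function(fvals) split(fvals$edges, fvals$edges$gene)

#' Signed directed protein network
#'
#' @param edges Data frame with columns `src`, `dst`, `sign` (+1/-1) and
#'   `weight` in (0, 1].
#' @param proteins Optional character vector of node ids (defaults to the ids
#'   present in `edges`).
#' @return An object of class `signed_network`.
#' @export
signed_network <- function(edges, proteins = NULL) {
  stopifnot(all(c("src", "dst", "sign", "weight") %in% names(edges)))
  if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
  if (any(edges$weight <= 0) || any(edges$weight > 1))
    stop("edge weights must lie in (0, 1]")
  if (any(edges$src == edges$dst)) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges$src, edges$dst)))
    stop("duplicate directed edges are not allowed")
  if (is.null(proteins)) proteins <- sort(unique(c(edges$src, edges$dst)))
  if (!all(c(edges$src, edges$dst) %in% proteins))
    stop("edge endpoints missing from protein list")
  structure(list(proteins = proteins,
                 edges = as.data.frame(edges)[, c("src", "dst", "sign", "weight")]),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d proteins, %d edges (%.0f%% inhibitory)\n",
              length(x$proteins), nrow(x$edges),
              100 * mean(x$edges$sign < 0)))
  invisible(x)
}
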