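# TSV readers/writers for the pipeline's interchange formats. All numeric
# output is formatted at 12 significant digits so round-trips are bit-stable
# at that precision and manifests hash identically across runs.

fmt_num <- function(x) sprintf("%.12g", x)

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, a header row of sample ids; the first column is `gene`.
#' When subtype or batch annotations are present they are written to a
#' sidecar `<path>.labels` TSV (sample, subtype, batch).
#'
#' @param expr An [expression_set] or matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  vals <- expr_values(expr)
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (inherits(expr, "expression_set") &&
      (!is.null(expr$subtype) || !is.null(expr$batch))) {
    lab <- data.frame(sample = colnames(vals),
                      subtype = if (is.null(expr$subtype)) NA else expr$subtype,
                      batch = if (is.null(expr$batch)) NA else expr$batch,
                      stringsAsFactors = FALSE)
    write_tsv(lab, paste0(path, ".labels"))
  }
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv]
#' @param path TSV path (sidecar `<path>.labels` picked up when present).
#' @return An [expression_set].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  subtype <- batch <- NULL
  lab_path <- paste0(path, ".labels")
  if (file.exists(lab_path)) {
    lab <- utils::read.table(lab_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(is.na(lab$subtype)))
      subtype <- stats::setNames(lab$subtype, lab$sample)
    if (!all(is.na(lab$batch)))
      batch <- stats::setNames(lab$batch, lab$sample)
  }
  expression_set(vals, subtype = subtype, batch = batch)
}

#' Write fitted F values as TSV
#'
#' Columns tf, gene, subtype, F, log2F; basal levels go to a sidecar
#' `<path>.basal` TSV (gene, basal). Values at 12 significant digits.
#'
#' @param fvals An [f_matrix].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_f_matrix <- function(fvals, path) {
  ed <- fvals$edges
  write_tsv(data.frame(tf = ed$tf, gene = ed$gene, subtype = fvals$subtype,
                       F = 2^ed$log2f, log2F = ed$log2f,
                       stringsAsFactors = FALSE), path)
  write_tsv(data.frame(gene = names(fvals$basal), basal = fvals$basal,
                       stringsAsFactors = FALSE), paste0(path, ".basal"))
  invisible(path)
}

#' Read an F-value TSV written by [write_f_matrix]
#' @param path TSV path (requires the sidecar `<path>.basal`).
#' @return An [f_matrix].
#' @export
read_f_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  basal_df <- utils::read.table(paste0(path, ".basal"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  f_matrix(data.frame(tf = df$tf, gene = df$gene, log2f = df$log2F,
                      stringsAsFactors = FALSE),
           stats::setNames(basal_df$basal, basal_df$gene),
           subtype = df$subtype[1])
}

#' Write a candidate network as TSV (tf, gene, provenance)
#' @param net A [candidate_network].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  write_tsv(as.data.frame(net), path)
}

#' Write a signed protein network as TSV (src, dst, sign, weight)
#' @param net A [signed_network].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(net, path) {
  write_tsv(net$edges, path)
}

#' Read a signed protein network TSV (src, dst, sign, weight)
#' @param path TSV path (header optional, detected).
#' @return A [signed_network].
#' @export
read_signed_network <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("src", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:4] <- c("src", "dst", "sign", "weight")
  signed_network(df)
}
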