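# Candidate-network assembly
#
# Builds the unsigned TF->gene backbone from binding-score tables (BED-like,
# 0-based half-open coordinates) and tissue regulatory networks: per-table
# score thresholding, closest-gene assignment within a TSS window, union
# across sources, and filtering to genes with expression data.

#' Read a BED6-like binding-score table
#'
#' Columns: chrom, start, end, name (TF id), score, \[strand\]. Coordinates
#' are 0-based half-open (BED dialect).
#'
#' @param path TSV file path (no header).
#' @return Data frame with columns `tf`, `chrom`, `start`, `end`, `score`.
#' @export
read_binding_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("binding-score table needs >= 5 columns (BED6-like)")
  out <- data.frame(tf = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    score = as.numeric(df[[5]]), stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("binding records must satisfy start < end")
  out
}

#' Read gene annotation with TSS coordinates
#'
#' BED format: chrom, start, end, gene_id, score, strand; the TSS is `start`
#' on the + strand and `end - 1` on the - strand (0-based). Minimal GTF is
#' also accepted (`gene` features; gene_id parsed from the attribute field;
#' GTF 1-based starts converted to 0-based).
#'
#' @param path File path.
#' @param format `"bed"` or `"gtf"`.
#' @return Data frame with columns `gene`, `chrom`, `tss`, `strand`
#'   (one row per gene).
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("gene BED needs 6 columns")
    out <- data.frame(gene = as.character(df[[4]]), chrom = as.character(df[[1]]),
                      tss = ifelse(df[[6]] == "-", as.integer(df[[3]]) - 1L,
                                   as.integer(df[[2]])),
                      strand = as.character(df[[6]]), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                            quote = "", stringsAsFactors = FALSE)
    df <- df[df[[3]] == "gene", , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df[[9]])
    out <- data.frame(gene = gid, chrom = as.character(df[[1]]),
                      tss = ifelse(df[[7]] == "-", as.integer(df[[5]]) - 1L,
                                   as.integer(df[[4]]) - 1L),
                      strand = as.character(df[[7]]), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene)) stop("annotation must have one TSS per gene")
  out
}

#' Retain the top-scoring fraction of binding records
#'
#' Keeps records whose score is at least the k-th largest where
#' `k = ceiling(top_fraction * n)`; ties at the cutoff are all retained, so
#' the retained count is always `>= ceiling(top_fraction * n)`.
#'
#' @param table Binding-score data frame (see [read_binding_scores]).
#' @param top_fraction Fraction in (0, 1] (reference analysis uses 0.10).
#' @return The filtered table.
#' @export
threshold_binding_scores <- function(table, top_fraction = 0.10) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  n <- nrow(table)
  if (n == 0) return(table)
  cutoff <- sort(table$score, decreasing = TRUE)[ceiling(top_fraction * n)]
  table[table$score >= cutoff, , drop = FALSE]
}

#' Assign motif occurrences to their closest genes
#'
#' Each record is summarized by its integer midpoint
#' `floor((start + end)/2)` and assigned to the gene(s) with minimal
#' |midpoint - TSS| among same-chromosome genes within `+-window_bp` of the
#' TSS. Equidistant ties go to all tied genes; records with no gene in range
#' produce no edge. Strand is ignored for the distance (the window is
#' symmetric); records on chromosomes absent from the annotation are skipped
#' with a warning.
#'
#' @param table Binding-score data frame.
#' @param genes Gene annotation data frame (see [read_gene_annotation]).
#' @param window_bp Positive window half-width (reference uses 10000).
#' @return A [candidate_network] with provenance `"binding"`.
#' @export
assign_motifs_to_genes <- function(table, genes, window_bp = 10000L) {
  if (window_bp <= 0) stop("window_bp must be positive")
  bad <- !(table$chrom %in% genes$chrom)
  if (any(bad)) {
    warning(sprintf("%d binding records on chromosomes absent from the annotation were skipped",
                    sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  if (nrow(table) == 0) return(candidate_network(provenance = "binding"))
  mid <- (table$start + table$end) %/% 2L
  tf_out <- character(0); gene_out <- character(0)
  for (chr in unique(table$chrom)) {
    ti <- which(table$chrom == chr)
    gi <- which(genes$chrom == chr)
    d <- abs(outer(mid[ti], genes$tss[gi], "-"))
    d[d > window_bp] <- NA_real_
    for (k in seq_along(ti)) {
      dk <- d[k, ]
      if (all(is.na(dk))) next
      hit <- gi[which(dk == min(dk, na.rm = TRUE))]
      tf_out <- c(tf_out, rep(table$tf[ti[k]], length(hit)))
      gene_out <- c(gene_out, genes$gene[hit])
    }
  }
  candidate_network(tf_out, gene_out, provenance = "binding")
}

#' Union of candidate networks
#'
#' Edge sets are unioned and provenance tags concatenated; idempotent and
#' invariant to the order of the input networks.
#'
#' @param nets List of [candidate_network] objects (at least one).
#' @return A [candidate_network].
#' @export
union_networks <- function(nets) {
  if (!length(nets)) stop("need at least one network")
  df <- do.call(rbind, lapply(nets, as.data.frame))
  candidate_network(df$tf, df$gene, df$provenance)
}

#' Filter a network to genes with expression data
#'
#' Retains edges whose TF and target both have rows in the expression
#' matrix.
#'
#' @param net A [candidate_network].
#' @param expr An [expression_set] or matrix with gene rownames.
#' @return The filtered [candidate_network].
#' @export
filter_by_expression <- function(net, expr) {
  present <- rownames(expr_values(expr))
  keep <- net$tf %in% present & net$gene %in% present
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tissue regulatory network edge list
#'
#' Three-column TSV (tf, target, weight); optionally retains only the top
#' weighted fraction of edges (rank rule with ties kept, as in
#' [threshold_binding_scores]).
#'
#' @param path TSV path (no header).
#' @param top_fraction Fraction of edges to retain by weight (default 1).
#' @param provenance Source tag for the resulting edges.
#' @return A [candidate_network].
#' @export
read_tissue_network <- function(path, top_fraction = 1, provenance = "tissue") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("tissue network needs 3 columns (tf, target, weight)")
  names(df)[1:3] <- c("tf", "gene", "weight")
  if (top_fraction < 1) {
    cutoff <- sort(df$weight, decreasing = TRUE)[ceiling(top_fraction * nrow(df))]
    df <- df[df$weight >= cutoff, , drop = FALSE]
  }
  candidate_network(df$tf, df$gene, provenance = provenance)
}
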