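# In-silico TF knockdown propagation (hPerturb)
#
# Knocking down a TF changes its targets' expression through the
# thermodynamic model; targets that are themselves TFs propagate the change
# onward. Because the model is steady-state, propagation is a single sweep
# in which each TF is perturbed at most once: a modified breadth-first
# traversal defers a downstream TF until all of its regulators on the path
# from the seed have been updated, and truncates feedback loops (a TF that
# has already been perturbed is never revisited; a TF whose deferral can
# never resolve because it sits on an unbroken cycle is left unperturbed).
# On acyclic regulatory graphs the schedule is exactly a topological order.
#
# Updates are applied as predicted log2 fold changes on the observed
# baseline: log2 new = log2 obs + sum_j [term_j(x_new) - term_j(x_base)],
# term_j(x) = log2((1 + F_j x)/(1 + x)). The basal level cancels, so a
# no-op knockdown (factor 1) reproduces the baseline exactly and residual
# structure of real data is preserved.

# TF->TF edge list of an f_matrix (targets that are themselves regulators).
tf_subgraph_edges <- function(fvals) {
  tfs <- f_tfs(fvals)
  ed <- fvals$edges[fvals$edges$gene %in% tfs, c("tf", "gene")]
  names(ed) <- c("from", "to")
  ed
}

tf_igraph <- function(fvals) {
  tfs <- f_tfs(fvals)
  ed <- tf_subgraph_edges(fvals)
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = tfs))
}

#' TFs that must not be perturbed at the current recursion step
#'
#' Given the TF currently being perturbed, returns the union of
#' (a) target TFs that have already been perturbed and show feedback
#' regulation of the current TF (a directed path from the target back to
#' it, including a self-loop), and (b) target TFs having a regulator on
#' the path from the topmost perturbed TF (i.e. reachable from it) that has
#' not yet been perturbed; those are deferred until their remaining on-path
#' regulators have been updated. The topmost and current TFs count as
#' perturbed regardless of `flags`.
#'
#' @param topmost The seed TF of the whole perturbation run.
#' @param current The TF whose targets are being examined.
#' @param graph TF-subnetwork edges: a data frame with columns `from`, `to`
#'   (or an igraph object).
#' @param flags Character vector of TFs already perturbed.
#' @return Character vector of target TFs to skip or defer at this step.
#' @export
do_not_perturb <- function(topmost, current, graph, flags = character(0)) {
  g <- if (inherits(graph, "igraph")) graph else
    igraph::graph_from_data_frame(graph, directed = TRUE)
  if (!current %in% igraph::V(g)$name) return(character(0))
  targets <- igraph::V(g)$name[
    igraph::adjacent_vertices(g, current, mode = "out")[[1]]]
  if (!length(targets)) return(character(0))
  eff_flags <- union(flags, c(topmost, current))
  reach_top <- igraph::V(g)$name[
    igraph::subcomponent(g, topmost, mode = "out")]
  skip <- character(0)
  for (u in unique(targets)) {
    if (u %in% eff_flags) {
      # (a) already perturbed: skip if it feeds back on the current TF
      # (a perturbed TF is never perturbed twice in any case)
      back <- igraph::V(g)$name[igraph::subcomponent(g, u, mode = "out")]
      if (current %in% back || u %in% flags) skip <- c(skip, u)
    } else {
      # (b) defer until all on-path regulators have been perturbed
      regs <- igraph::V(g)$name[
        igraph::adjacent_vertices(g, u, mode = "in")[[1]]]
      pending <- setdiff(intersect(regs, reach_top), eff_flags)
      if (length(pending)) skip <- c(skip, u)
    }
  }
  unique(skip)
}

# Deterministic update schedule for the TFs reachable from the seed.
# Kahn-style worklist: a TF becomes ready when all of its regulators inside
# the reachable set have been finalized (the seed starts finalized); ready
# TFs are processed by (BFS distance from the seed, name). TFs whose
# deferral never resolves (unbroken cycles) are excluded and logged, as are
# feedback edges into already-finalized TFs.
perturb_schedule <- function(fvals, seed_tf) {
  g <- tf_igraph(fvals)
  if (!seed_tf %in% igraph::V(g)$name)
    g <- igraph::add_vertices(g, 1, name = seed_tf)
  reach <- igraph::V(g)$name[igraph::subcomponent(g, seed_tf, mode = "out")]
  sub <- igraph::induced_subgraph(g, reach)
  ed <- igraph::as_data_frame(sub, what = "edges")
  dist <- igraph::distances(sub, v = seed_tf, mode = "out")[1, reach]
  pending <- vapply(reach, function(u)
    length(setdiff(unique(ed$from[ed$to == u]), seed_tf)), integer(1))
  names(pending) <- reach
  finalized <- seed_tf
  ready <- setdiff(reach[pending == 0], seed_tf)
  order <- character(0)
  truncations <- data.frame(tf = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
  while (length(ready)) {
    ready <- ready[order(dist[ready], ready)]
    u <- ready[1]; ready <- ready[-1]
    order <- c(order, u)
    finalized <- c(finalized, u)
    for (v in unique(ed$to[ed$from == u])) {
      if (v %in% finalized) {
        truncations <- rbind(truncations, data.frame(
          tf = v, reason = sprintf("feedback from %s truncated", u),
          stringsAsFactors = FALSE))
      } else {
        pending[v] <- pending[v] - 1L
        if (pending[v] == 0L) ready <- c(ready, v)
      }
    }
  }
  stalled <- setdiff(reach, finalized)
  if (length(stalled))
    truncations <- rbind(truncations, data.frame(
      tf = stalled, reason = "unresolvable cycle: left unperturbed",
      stringsAsFactors = FALSE))
  list(order = order, skipped = stalled, truncations = truncations)
}

# Recompute one gene's expression as baseline times the model's predicted
# fold change between two regulator states (vectorized over samples).
apply_fold_change <- function(baseline_row, edges, x_new, x_base) {
  delta <- colSums(fold_change_log2(edges$log2f, x_new)) -
    colSums(fold_change_log2(edges$log2f, x_base))
  out <- 2^(log2(pmax(baseline_row, .Machine$double.xmin)) + delta)
  out[delta == 0] <- baseline_row[delta == 0]  # exact no-op, no log round-trip
  out[baseline_row == 0] <- 0
  out
}

#' Simulate a TF knockdown and propagate it through the network
#'
#' Multiplies the seed TF's expression by `knockdown_factor` and updates all
#' downstream genes through the regulatory model (see the scheduling and
#' fold-change semantics described above). Every gene is updated at most
#' once beyond the seed; genes not reachable from the seed are unchanged;
#' the algorithm terminates on any finite graph.
#'
#' @param fvals An [f_matrix].
#' @param expr An [expression_set] or matrix holding baseline expression of
#'   all genes and TFs (vectorized over its samples).
#' @param tf The TF to knock down (must be a regulator in `fvals`).
#' @param knockdown_factor Multiplier in \[0, 1\] applied to the seed TF's
#'   expression; 0 (full silencing) by default; 1 is the identity
#'   perturbation and reproduces the baseline.
#' @return Object of class `perturbation_result`: list with
#'   `new_expression` (full matrix), `updated_genes` (ordered character
#'   vector, seed first), `loop_truncations` (data frame tf, reason).
#' @export
h_perturb <- function(fvals, expr, tf, knockdown_factor = 0) {
  vals <- expr_values(expr)
  if (!tf %in% f_tfs(fvals)) stop("unknown TF: ", tf)
  if (!tf %in% rownames(vals)) stop("no expression row for TF ", tf)
  if (knockdown_factor < 0 || knockdown_factor > 1)
    stop("knockdown_factor must be in [0, 1]")
  baseline <- vals
  cur <- vals
  cur[tf, ] <- cur[tf, ] * knockdown_factor
  sched <- perturb_schedule(fvals, tf)
  by_gene <- f_by_gene(fvals)
  updated <- c(tf, sched$order)
  # TFs in schedule order: each recomputed once from current regulator state
  for (u in sched$order) {
    ed <- by_gene[[u]]
    if (is.null(ed)) next  # no incoming regulatory edges
    cur[u, ] <- apply_fold_change(baseline[u, ], ed,
                                  cur[ed$tf, , drop = FALSE],
                                  baseline[ed$tf, , drop = FALSE])
  }
  # final pass: non-TF targets of any updated regulator
  tf_set <- f_tfs(fvals)
  affected <- setdiff(unique(fvals$edges$gene[fvals$edges$tf %in% updated]),
                      tf_set)
  affected <- sort(intersect(affected, rownames(cur)))
  for (gn in affected) {
    ed <- by_gene[[gn]]
    cur[gn, ] <- apply_fold_change(baseline[gn, ], ed,
                                   cur[ed$tf, , drop = FALSE],
                                   baseline[ed$tf, , drop = FALSE])
  }
  structure(list(new_expression = cur,
                 updated_genes = c(updated, affected),
                 loop_truncations = sched$truncations,
                 tf = tf, knockdown_factor = knockdown_factor),
            class = "perturbation_result")
}

#' Knock down every TF in turn
#'
#' Runs [h_perturb] independently for each TF of the model from the same
#' baseline expression; failures are isolated per TF and reported.
#'
#' @param fvals An [f_matrix].
#' @param expr Baseline expression.
#' @param knockdown_factor Passed to [h_perturb].
#' @return Named list of `perturbation_result` objects (a failed TF holds a
#'   list with an `error` message instead).
#' @export
perturb_all_tfs <- function(fvals, expr, knockdown_factor = 0) {
  tfs <- f_tfs(fvals)
  out <- stats::setNames(vector("list", length(tfs)), tfs)
  for (tf in tfs) {
    out[[tf]] <- tryCatch(h_perturb(fvals, expr, tf, knockdown_factor),
                          error = function(e)
                            list(tf = tf, error = conditionMessage(e)))
  }
  out
}

#' Log2 fold changes of a perturbation result
#' @param result A `perturbation_result`.
#' @param expr The baseline expression used for the run.
#' @return Matrix of log2(new/baseline), zeros where both are zero.
#' @export
perturbation_log2fc <- function(result, expr) {
  base <- expr_values(expr)
  new <- result$new_expression
  lfc <- log2(pmax(new, .Machine$double.xmin) /
                pmax(base, .Machine$double.xmin))
  lfc[new == 0 & base == 0] <- 0
  lfc
}
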