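# End-to-end pipeline orchestration on synthetic cohorts
#
# Stages: simulate -> fit (per subtype) -> signatures + coregulation ->
# perturb -> rank -> essentiality. Every stage derives its seed
# deterministically from the global seed, writes TSV outputs into its own
# subdirectory and records file hashes and parameters in a manifest, so a
# rerun with the same config is byte-identical.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable stage parameter;
#' override entries via `run_pipeline(config = modifyList(default_pipeline_config(), ...))`
#' or by passing a YAML file path.
#'
#' @param out_dir Run directory.
#' @param seed Global integer seed; all stage seeds derive from it.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir = "regcap_run", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c(simulate = TRUE, fit = TRUE, signatures = TRUE,
               coreg = TRUE, perturb = TRUE, rank = TRUE,
               essentiality = TRUE),
    simulate = list(n_tfs = 4L, n_genes = 14L, subtypes = c("A", "B"),
                    edge_density = 0.5, frac_signature_edges = 0.25,
                    noise_sd = 0.1, samples_per_subtype = 30L),
    fit = list(lambda = 0.1, max_iter = 500L, grad_tol = 1e-6, folds = 5L),
    signatures = list(n_shuffles = 8L, sd_threshold = 5),
    coreg = list(min_inlier_fraction = 0.8, top_fraction = 0.1),
    perturb = list(knockdown_factor = 0),
    rank = list(tolerance = 1e-6, max_iter = 10000L,
                n_edges = 60L, frac_inhibitory = 0.3),
    essentiality = list(train_fraction = 0.75, cv_folds = 4L,
                        n_true_predictors = 3L, coef_scale = 1,
                        noise_sd = 0.05)
  ), class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(default_pipeline_config(), user)
  } else if (is.list(config)) {
    config <- utils::modifyList(default_pipeline_config(), config)
  } else stop("config must be a list or a YAML file path")
  config
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 101L, fit = 202L, signatures = 303L, coreg = 404L,
               perturb = 505L, rank = 606L, essentiality = 707L)
  (config$seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the enabled stages in order, writing each stage's outputs and a
#' `manifest.json` (parameters, stage seeds, MD5 hashes of every output
#' file) into `out_dir`. A rerun with an identical config reproduces
#' identical outputs and manifest. Disabled stages are skipped; downstream
#' stages consume the outputs already present in `out_dir` from a previous
#' run.
#'
#' @param config A list (merged over [default_pipeline_config]) or a YAML
#'   file path.
#' @return The run directory, invisibly; the manifest is also returned as
#'   attribute `"manifest"`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- load_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "regcap",
                   version = as.character(utils::packageVersion("regcap")),
                   seed = cfg$seed, stages = list())
  log_msg <- function(...) message(sprintf(...))

  sdir <- function(name) {
    d <- file.path(out, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  finish_stage <- function(name, params, files) {
    hashes <- as.list(tools::md5sum(files))
    names(hashes) <- basename(files)
    manifest$stages[[name]] <<- list(seed = stage_seed(cfg, name),
                                     params = params, files = hashes)
  }

  ## simulate ----------------------------------------------------------
  d <- sdir("simulate")
  sim_files <- file.path(d, c("expression.tsv", "expression.tsv.labels",
                              "truth_f.tsv", "truth_f.tsv.basal",
                              "protein_net.tsv"))
  if (cfg$stages[["simulate"]]) {
    log_msg("stage simulate: generating ground truth and cohort")
    p <- cfg$simulate
    truth <- generate_regulatory_truth(p$n_tfs, p$n_genes, p$subtypes,
                                       p$edge_density,
                                       p$frac_signature_edges,
                                       p$noise_sd,
                                       seed = stage_seed(cfg, "simulate"))
    expr <- simulate_cohort(truth, p$samples_per_subtype,
                            seed = stage_seed(cfg, "simulate") + 1L)
    # signed signaling net over the cohort's own gene products, so ranking
    # can consume (perturbed) expression directly
    ids <- rownames(expr$values)
    raw_net <- generate_signed_protein_network(length(ids),
                                               min(cfg$rank$n_edges,
                                                   length(ids) * (length(ids) - 1L)),
                                               cfg$rank$frac_inhibitory,
                                               seed = stage_seed(cfg, "simulate") + 2L)
    map <- stats::setNames(ids, raw_net$proteins)
    net <- signed_network(data.frame(src = unname(map[raw_net$edges$src]),
                                     dst = unname(map[raw_net$edges$dst]),
                                     sign = raw_net$edges$sign,
                                     weight = raw_net$edges$weight,
                                     stringsAsFactors = FALSE),
                          proteins = unname(map))
    write_expression_tsv(expr, sim_files[1])
    truth_df <- truth$f
    write_tsv(truth_df, sim_files[3])
    write_tsv(data.frame(gene = names(truth$basal), basal = truth$basal,
                         stringsAsFactors = FALSE), sim_files[4])
    write_signed_network(net, sim_files[5])
    finish_stage("simulate", p, sim_files)
  } else {
    log_msg("stage simulate: skipped, reusing %s", d)
    expr <- read_expression_tsv(sim_files[1])
    net <- read_signed_network(sim_files[5])
  }
  backbone <- {
    tdf <- utils::read.table(sim_files[3], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    candidate_network(tdf$tf, tdf$gene, provenance = "truth")
  }
  subtypes <- sort(unique(expr$subtype))

  ## fit ----------------------------------------------------------------
  d <- sdir("fit")
  fit_files <- as.character(vapply(subtypes, function(s)
    file.path(d, sprintf("fvalues_%s.tsv", s)), character(1)))
  if (cfg$stages[["fit"]]) {
    log_msg("stage fit: fitting %d subtype model(s)", length(subtypes))
    fcfg <- fit_config(lambda = cfg$fit$lambda, max_iter = cfg$fit$max_iter,
                       grad_tol = cfg$fit$grad_tol, folds = cfg$fit$folds,
                       seed = stage_seed(cfg, "fit"))
    models <- lapply(subtypes, function(s)
      fit_subtype_model(backbone, expr, s, fcfg)$fvals)
    names(models) <- subtypes
    for (i in seq_along(subtypes))
      write_f_matrix(models[[i]], fit_files[i])
    finish_stage("fit", cfg$fit,
                 c(fit_files, paste0(fit_files, ".basal")))
  } else {
    log_msg("stage fit: skipped, reusing %s", d)
    models <- lapply(fit_files, read_f_matrix)
    names(models) <- subtypes
  }

  ## signatures ----------------------------------------------------------
  d <- sdir("signatures")
  sig_files <- file.path(d, c("signature_edges.tsv", "participation.tsv"))
  if (cfg$stages[["signatures"]]) {
    log_msg("stage signatures: %d label shuffles", cfg$signatures$n_shuffles)
    fcfg <- fit_config(lambda = cfg$fit$lambda, seed = stage_seed(cfg, "signatures"))
    null <- permute_and_refit(backbone, expr,
                              n_shuffles = cfg$signatures$n_shuffles,
                              seed = stage_seed(cfg, "signatures"),
                              config = fcfg)
    calls <- call_signature_edges(models, null,
                                  sd_threshold = cfg$signatures$sd_threshold)
    part <- participation_scores(calls, subtypes = subtypes)
    write_tsv(as.data.frame(calls), sig_files[1])
    write_tsv(data.frame(tf = rownames(part),
                         as.data.frame(part, check.names = FALSE),
                         stringsAsFactors = FALSE, check.names = FALSE),
              sig_files[2])
    finish_stage("signatures", cfg$signatures, sig_files)
  } else log_msg("stage signatures: skipped")

  ## coregulation --------------------------------------------------------
  d <- sdir("coreg")
  coreg_files <- file.path(d, sprintf("correlation_%s.tsv", subtypes))
  if (cfg$stages[["coreg"]]) {
    log_msg("stage coreg: all-pairs robust correlation")
    for (i in seq_along(subtypes)) {
      corr <- all_pairs_coregulation(models[[i]],
                                     min_inlier_fraction = cfg$coreg$min_inlier_fraction,
                                     seed = stage_seed(cfg, "coreg"))
      write_tsv(data.frame(tf = rownames(corr$r),
                           as.data.frame(corr$r, check.names = FALSE),
                           check.names = FALSE, stringsAsFactors = FALSE),
                coreg_files[i])
    }
    finish_stage("coreg", cfg$coreg, coreg_files)
  } else log_msg("stage coreg: skipped")

  ## perturb -------------------------------------------------------------
  d <- sdir("perturb")
  fv1 <- models[[1]]
  tfs <- f_tfs(fv1)
  pert_files <- file.path(d, sprintf("log2fc_%s.tsv", tfs))
  if (cfg$stages[["perturb"]]) {
    log_msg("stage perturb: knocking down %d TFs", length(tfs))
    perts <- perturb_all_tfs(fv1, expr, cfg$perturb$knockdown_factor)
    for (i in seq_along(tfs)) {
      lfc <- perturbation_log2fc(perts[[tfs[i]]], expr)
      write_tsv(data.frame(gene = rownames(lfc), lfc, check.names = FALSE,
                           stringsAsFactors = FALSE), pert_files[i])
    }
    finish_stage("perturb", cfg$perturb, pert_files)
  } else {
    log_msg("stage perturb: skipped, reusing %s", d)
    perts <- NULL
  }

  ## rank ----------------------------------------------------------------
  d <- sdir("rank")
  rank_file <- file.path(d, "activity_deltas.tsv")
  if (cfg$stages[["rank"]]) {
    log_msg("stage rank: Exponential Ranking per TF and sample")
    if (is.null(perts)) perts <- perturb_all_tfs(fv1, expr,
                                                 cfg$perturb$knockdown_factor)
    deltas <- activity_delta_table(net, expr, perts,
                                   tolerance = cfg$rank$tolerance,
                                   max_iter = cfg$rank$max_iter)
    long <- do.call(rbind, lapply(names(deltas), function(tf)
      data.frame(tf = tf, sample = rownames(deltas[[tf]]),
                 deltas[[tf]], check.names = FALSE,
                 stringsAsFactors = FALSE)))
    write_tsv(long, rank_file)
    finish_stage("rank", cfg$rank[c("tolerance", "max_iter")], rank_file)
  } else {
    log_msg("stage rank: skipped, reusing %s", d)
    long <- utils::read.table(rank_file, sep = "\t", header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
    deltas <- lapply(split(long, long$tf), function(df) {
      m <- as.matrix(df[, -(1:2), drop = FALSE])
      rownames(m) <- df$sample
      m
    })
  }

  ## essentiality --------------------------------------------------------
  d <- sdir("essentiality")
  ess_files <- file.path(d, c("measured.tsv", "models.tsv", "report.tsv"))
  if (cfg$stages[["essentiality"]]) {
    log_msg("stage essentiality: per-TF elastic nets")
    p <- cfg$essentiality
    sim <- simulate_essentiality(deltas, p$n_true_predictors, p$coef_scale,
                                 p$noise_sd,
                                 seed = stage_seed(cfg, "essentiality"))
    emods <- lapply(names(deltas), function(tf)
      train_essentiality_model(tf, deltas[[tf]], sim$scores[tf, ],
                               train_fraction = p$train_fraction,
                               cv_folds = p$cv_folds,
                               seed = stage_seed(cfg, "essentiality") + 1L))
    names(emods) <- names(deltas)
    write_tsv(data.frame(tf = rownames(sim$scores), sim$scores,
                         check.names = FALSE, stringsAsFactors = FALSE),
              ess_files[1])
    coef_long <- do.call(rbind, lapply(emods, function(m)
      data.frame(tf = m$tf, protein = names(m$coefficients),
                 coefficient = m$coefficients, stringsAsFactors = FALSE)))
    write_tsv(coef_long, ess_files[2])
    write_tsv(essentiality_report(emods), ess_files[3])
    finish_stage("essentiality", p, ess_files)
  } else log_msg("stage essentiality: skipped")

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  structure(invisible(out), manifest = manifest)
}

#' Activity deltas for a set of perturbations
#'
#' For every sample, ranks the baseline expression on the signed protein
#' network, then re-ranks each TF-knockdown expression profile and records
#' the per-protein change in signed-log activity. Network proteins are
#' matched to expression rows by id; expression vectors are scaled to sum 1
#' as the ranking's start vector and used to augment the transition matrix.
#'
#' @param net A [signed_network] whose proteins are (a subset of) the
#'   expression rows.
#' @param expr Baseline [expression_set].
#' @param perturbations Named list of `perturbation_result`s (per TF).
#' @param tolerance,max_iter Passed to [exponential_ranking].
#' @return Named list per TF of sample x protein delta matrices.
#' @export
activity_delta_table <- function(net, expr, perturbations,
                                 tolerance = 1e-6, max_iter = 10000L) {
  vals <- expr_values(expr)
  prots <- intersect(net$proteins, rownames(vals))
  if (length(prots) < length(net$proteins))
    stop("expression rows missing for some network proteins")
  samples <- colnames(vals)
  base_scores <- lapply(samples, function(s) {
    x <- vals[net$proteins, s]
    rank_profile(net, x, tolerance, max_iter)
  })
  names(base_scores) <- samples
  out <- lapply(perturbations, function(pert) {
    if (!is.null(pert$error)) return(NULL)
    m <- matrix(NA_real_, length(samples), length(net$proteins),
                dimnames = list(samples, net$proteins))
    for (s in samples) {
      x <- pert$new_expression[net$proteins, s]
      sc <- rank_profile(net, x, tolerance, max_iter)
      m[s, ] <- activity_delta(base_scores[[s]], sc)
    }
    m
  })
  out[!vapply(out, is.null, logical(1))]
}

# Rank one expression profile: scale to sum 1, build A, iterate.
rank_profile <- function(net, x, tolerance, max_iter) {
  x <- pmax(x, 1e-9)  # ranking needs positive start weights
  trans <- build_transition_matrix(net, x)
  exponential_ranking(trans, p0 = x / sum(x), tolerance = tolerance,
                      max_iter = max_iter)
}
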