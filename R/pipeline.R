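#' Configuration of a full pipeline run
#'
#' One global seed is fanned out into stable stage-specific child seeds
#' so that stages can be re-run in isolation and two runs with the same
#' configuration are byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param seed global RNG seed.
#' @param stages stages to run, in order, among `"simulate"`,
#'   `"preprocess"`, `"test"`, `"cluster"`, `"enrich"`, `"kinetics"`.
#' @param n_genes_per_archetype,n_housekeeping,n_null generator sizes.
#' @param noise a [noise_spec()] (its seed is overridden by the fan-out).
#' @param k number of expression clusters (default 7).
#' @param n_permutations permutations for the significance test.
#' @param p_threshold significance p-value cut-off.
#' @param enrichment_threshold raw hypergeometric p cut-off (default 1e-6).
#' @param motif IUPAC motif scanned in promoters.
#' @param params kinetic [retentostat_params()].
#' @return a `run_config` list.
#' @export
run_config <- function(outdir = tempfile("nearzero_run_"), seed = 1,
                       stages = c("simulate", "preprocess", "test",
                                  "cluster", "enrich", "kinetics"),
                       n_genes_per_archetype = 60, n_housekeeping = 30,
                       n_null = 400, noise = noise_spec(), k = 7,
                       n_permutations = 1000, p_threshold = 0.01,
                       enrichment_threshold = 1e-6, motif = "TCGTTYAG",
                       params = retentostat_params()) {
  known <- c("simulate", "preprocess", "test", "cluster", "enrich",
             "kinetics")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(outdir = outdir, seed = seed, stages = stages,
                 n_genes_per_archetype = n_genes_per_archetype,
                 n_housekeeping = n_housekeeping, n_null = n_null,
                 noise = noise, k = k, n_permutations = n_permutations,
                 p_threshold = p_threshold,
                 enrichment_threshold = enrichment_threshold,
                 motif = motif, params = params),
            class = "run_config")
}

child_seed <- function(seed, stage_index) {
  (abs(seed) * 97 + stage_index * 1009) %% 2147483647L
}

stage_log <- function(stage, ...) {
  message(sprintf("[nearzero:%s] %s", stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the simulate-to-kinetics pipeline
#'
#' Executes the enabled stages in order — synthetic-data generation,
#' expression preprocessing, growth-rate significance testing,
#' correlation-distance clustering, gene-set and motif enrichment, and
#' retentostat kinetics — writing every intermediate table under
#' `config$outdir` and returning a summary report (also written as
#' `report.json`). Runs are idempotent at a fixed seed.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with per-stage counts and the kinetic
#'   summary.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  report <- list(seed = config$seed, stages = config$stages,
                 package_version = as.character(utils::packageVersion("nearzero")))
  st <- function(s) s %in% config$stages

  mat <- meta <- truth <- sets <- promoters <- series <- NULL
  if (st("simulate")) run_stage("simulate", {
    noise <- config$noise
    noise$seed <- child_seed(config$seed, 1)
    sim <- generate_expression(design_spec(),
                               n_genes_per_archetype = config$n_genes_per_archetype,
                               n_housekeeping = config$n_housekeeping,
                               n_null = config$n_null, noise = noise)
    mat <- sim$matrix; meta <- sim$metadata; truth <- sim$truth
    classes <- unique(truth$class[truth$responder])
    planted <- data.frame(set_name = paste0("planted_", classes),
                          class = classes, odds = 8)
    gs <- generate_gene_sets(truth, planted, n_decoys = 10,
                             set_size = min(100, nrow(truth)),
                             seed = child_seed(config$seed, 2))
    sets <- gs$collection
    motif_targets <- truth$gene_id[truth$class == "retentostat_down"]
    promoters <- generate_promoters(truth$gene_id, motif = config$motif,
                                     p_background = 0.1, p_planted = 0.4,
                                     planted_genes = motif_targets,
                                     seed = child_seed(config$seed, 3))
    series <- generate_retentostat_series(config$params,
                                           noise_cv = 0.02,
                                           seed = child_seed(config$seed, 4))
    write_expression_matrix(mat, out("expression.tsv"))
    write_tsv(meta, out("metadata.tsv"))
    write_tsv(truth, out("truth.tsv"))
    write_gmt(sets, out("gene_sets.gmt"))
    Biostrings::writeXStringSet(promoters, out("promoters.fa"))
    write_tsv(data.frame(time_h = series$series$time_h,
                         cx_total_g_per_l = series$series$cx_total,
                         viability_fraction = series$series$viability),
              out("series.tsv"))
    write_tsv(series$truth, out("series_truth.tsv"))
    report$simulate <- list(n_genes = nrow(mat), n_samples = ncol(mat))
    stage_log("simulate", nrow(mat), " genes x ", ncol(mat), " samples")
  })

  clean <- NULL
  if (st("preprocess")) run_stage("preprocess", {
    if (is.null(mat)) {
      mat <- read_expression_matrix(out("expression.tsv"))
      meta <- read_sample_metadata(out("metadata.tsv"))
    }
    check_sample_metadata(meta, mat)
    scaled <- global_scale(mat)
    ff <- floor_and_filter(scaled)
    clean <- ff$matrix
    write_expression_matrix(clean, out("clean.tsv"))
    report$preprocess <- list(genes_in = nrow(mat),
                              genes_out = nrow(clean),
                              removed = length(ff$removed))
    stage_log("preprocess", nrow(clean), " of ", nrow(mat), " genes kept")
  })

  sig <- results <- NULL
  if (st("test")) run_stage("test", {
    cfg <- test_config(n_permutations = config$n_permutations,
                       seed = child_seed(config$seed, 5),
                       p_threshold = config$p_threshold)
    results <- run_significance(clean, meta, cfg)
    sig <- call_significant(results, cfg)
    write_tsv(results, out("test_results.tsv"))
    report$test <- list(genes_tested = nrow(results),
                        significant = nrow(sig),
                        pi0 = as.numeric(attr(results, "pi0")))
    stage_log("test", nrow(sig), " significant genes of ", nrow(results))
  })

  km <- profiles <- NULL
  if (st("cluster")) run_stage("cluster", {
    profiles <- mean_normalize_profiles(clean[sig$gene_id, , drop = FALSE],
                                         meta)
    km <- kmeans_correlation(profiles, k = config$k,
                              seed = child_seed(config$seed, 6))
    write_tsv(data.frame(gene_id = names(km$cluster),
                         cluster = as.integer(km$cluster)),
              out("clusters.tsv"))
    write_expression_matrix(km$centroids, out("centroids.tsv"),
                            id_column = "cluster")
    report$cluster <- list(k = km$k, objective = km$objective,
                           sizes = as.integer(table(factor(km$cluster,
                                                           levels = seq_len(km$k)))))
    stage_log("cluster", "objective ", signif(km$objective, 4))
  })

  if (st("enrich")) run_stage("enrich", {
    universe <- rownames(clean)
    coll <- gene_set_collection(sets$sets, universe)
    by_cluster <- split(names(km$cluster), km$cluster)
    enr <- do.call(rbind, lapply(names(by_cluster), function(cl)
      data.frame(cluster = cl,
                 hypergeometric_enrichment(by_cluster[[cl]], coll,
                                           config$enrichment_threshold))))
    write_tsv(enr, out("enrichment.tsv"))
    hits <- scan_motif(promoters[universe], config$motif)
    mef <- do.call(rbind, lapply(names(by_cluster), function(cl) {
      r <- motif_enrichment_factor(by_cluster[[cl]], hits, universe)
      data.frame(cluster = cl, ef = r$ef, p = r$p, k = r$k, n = r$n)
    }))
    write_tsv(mef, out("motif_ef.tsv"))
    report$enrich <- list(significant_sets = sum(enr$significant),
                          max_motif_ef = max(mef$ef, na.rm = TRUE))
    stage_log("enrich", sum(enr$significant), " significant cluster/set pairs")
  })

  if (st("kinetics")) run_stage("kinetics", {
    if (is.null(series))
      series <- list(series = read_biomass_series(out("series.tsv")))
    fit <- fit_biomass_curve(series$series)
    prof <- specific_growth_rate(fit, series$series)
    part <- glucose_partition(config$params, prof$cx_viable, prof$mu)
    write_tsv(cbind(prof, part[, c("frac_maintenance", "frac_growth")]),
              out("growth_profile.tsv"))
    jsonlite::write_json(fit[c("A", "B", "C", "sse", "converged")],
                         out("fit.json"), auto_unbox = TRUE, digits = NA)
    final <- nrow(prof)
    report$kinetics <- list(A = fit$A, B = fit$B, C = fit$C,
                            final_mu = prof$mu[final],
                            final_doubling_time_h = doubling_time(prof$mu[final]),
                            final_frac_maintenance = part$frac_maintenance[final])
    stage_log("kinetics", "final mu ", signif(prof$mu[final], 3), " /h")
  })

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("nearzero pipeline report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$test))
    cat("  significant genes: ", x$test$significant, " / ",
        x$test$genes_tested, "\n", sep = "")
  if (!is.null(x$cluster))
    cat("  cluster sizes: ", paste(x$cluster$sizes, collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$kinetics))
    cat(sprintf("  final mu %.3g /h (doubling time %.0f h), maintenance fraction %.2f\n",
                x$kinetics$final_mu, x$kinetics$final_doubling_time_h,
                x$kinetics$final_frac_maintenance))
  invisible(x)
}
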