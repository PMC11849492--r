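#' Build a pipeline configuration
#'
#' Collects every stage parameter (with the package defaults) and the
#' output directory into a validated configuration object. All seeds are
#' materialized at construction so a configuration fully determines a run.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master integer seed (also seeds the simulation unless a
#'   `sim` configuration is supplied).
#' @param input_dir Optional directory of a pre-existing study (written by
#'   [write_study()]); when `NULL` the cohort is simulated.
#' @param sim A [sim_config()] for the simulate stage.
#' @param folds,trees Random-forest cross-validation parameters.
#' @param permutations PERMANOVA permutation count for the pipeline run
#'   (default 999; the standalone [permanova()] default is 9999).
#' @param correlation_threshold Canopy clustering Pearson radius.
#' @param min_genes MGS gene-count threshold (strict; default 50, suited
#'   to desk-scale synthetic cohorts — production-scale catalogs use 500).
#' @param min_kos,fdr_threshold Module-SIP test parameters.
#' @param driver_module,driver_sip Module id and SIP for the drivers stage;
#'   default (`NULL`) uses the study truth's target module and SIP when
#'   simulating, else the most significant module association.
#' @return An object of class `dermalink_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, input_dir = NULL,
                            sim = sim_config(seed = seed), folds = 5,
                            trees = 500, permutations = 999,
                            correlation_threshold = 0.9, min_genes = 50,
                            min_kos = 3, fdr_threshold = 0.05,
                            driver_module = NULL, driver_sip = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              input_dir = input_dir, sim = sim, folds = folds, trees = trees,
              permutations = permutations,
              correlation_threshold = correlation_threshold,
              min_genes = min_genes, min_kos = min_kos,
              fdr_threshold = fdr_threshold, driver_module = driver_module,
              driver_sip = driver_sip)
  class(cfg) <- "dermalink_pipeline_config"
  cfg
}

.validate_pipeline_config <- function(config) {
  if (inherits(config, "dermalink_pipeline_config")) config <- unclass(config)
  if (!is.list(config)) stop("config must be a list")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("out_dir is required")
  do.call(pipeline_config, config[intersect(names(config), known)])
}

#' Run the full metagenome-phenome pipeline
#'
#' Executes the stages in dependency order — simulate (or load), phenome
#' dynamics, skin-age indices, diversity, MGS construction, module-SIP
#' association, driver attribution — writing every declared output table
#' under `out_dir` plus a `manifest.tsv` of file MD5 hashes and a `run.log`
#' recording every seed and threshold used. An identical configuration
#' produces byte-identical outputs and hence an identical manifest.
#'
#' @param config A [pipeline_config()] (or plain named list with the same
#'   keys; unknown keys are rejected).
#' @return Invisibly, the manifest data.frame (`file`, `md5`). If a stage
#'   fails, the manifest of files written so far is still saved, with the
#'   failure recorded in `run.log`, before the error is re-signalled.
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  cat("", file = logf)
  log_line <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  log_line("seed=", cfg$seed, " folds=", cfg$folds, " trees=", cfg$trees,
           " permutations=", cfg$permutations,
           " correlation_threshold=", cfg$correlation_threshold,
           " min_genes=", cfg$min_genes, " min_kos=", cfg$min_kos,
           " fdr_threshold=", cfg$fdr_threshold)
  if (!is.null(cfg$input_dir)) {
    needed <- file.path(cfg$input_dir,
                        c("metadata.tsv", "phenome.tsv", "species.tsv",
                          "genes.tsv", "gene2ko.tsv", "gene2taxon.tsv",
                          "modules.tsv", "lineage.tsv", "truth.json"))
    missing <- needed[!file.exists(needed)]
    if (length(missing) > 0)
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }

  p <- function(f) file.path(out, f)
  written <- character(0)
  emit_df <- function(df, f) { .write_tsv_df(df, p(f)); written <<- c(written, f) }
  emit_mat <- function(m, f) { write_abundance_table(m, p(f)); written <<- c(written, f) }

  finish <- function() {
    files <- sort(unique(c(written, "run.log")))
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(file.path(out, files))),
                           stringsAsFactors = FALSE)
    .write_tsv_df(manifest, p("manifest.tsv"))
    manifest
  }

  result <- tryCatch({
    ## simulate / load -----------------------------------------------------
    if (is.null(cfg$input_dir)) {
      log_line("stage simulate: sim seed=", cfg$sim$seed)
      study <- generate_cohort(cfg$sim)
      write_study(study, file.path(out, "study"), overwrite = TRUE)
      written <- c(written, file.path("study", list.files(file.path(out, "study"))))
    } else {
      log_line("stage load: ", cfg$input_dir)
      study <- read_study(cfg$input_dir)
    }
    ages <- study$metadata$age
    phen <- study$phenome

    ## phenome dynamics ----------------------------------------------------
    log_line("stage phenome")
    emit_df(sip_age_regression(phen, study$metadata), "trends.tsv")
    pca <- phenome_pca(phen)
    sc <- t(pca$scores)
    colnames(sc) <- study$metadata$sample_id
    emit_mat(sc, "pca_scores.tsv")
    emit_mat(t(pca$loadings), "pca_loadings.tsv")

    ## skin-age indices ----------------------------------------------------
    log_line("stage ages: rf seed=", cfg$seed)
    sip_mat <- as.matrix(phen[, .sip_names()])
    spa <- fit_age_index(sip_mat, ages, cfg$folds, cfg$trees, seed = cfg$seed)
    sma <- fit_age_index(t(study$species), ages, cfg$folds, cfg$trees,
                         seed = cfg$seed)
    sia <- fit_age_index(cbind(scale(sip_mat), t(study$species)), ages,
                         cfg$folds, cfg$trees, seed = cfg$seed)
    emit_df(data.frame(sample_id = study$metadata$sample_id, age = ages,
                       spa = spa$predicted_age, sma = sma$predicted_age,
                       sia = sia$predicted_age), "ages.tsv")
    emit_df(data.frame(index = "spa", feature = .sip_names(),
                       importance = spa$importance$mean,
                       importance_sd = spa$importance$sd), "importance.tsv")

    ## diversity -----------------------------------------------------------
    log_line("stage diversity: permutations=", cfg$permutations,
             " seed=", cfg$seed)
    alpha <- shannon(study$species)
    emit_df(data.frame(sample_id = names(alpha), shannon = unname(alpha)),
            "alpha.tsv")
    bc <- bray_curtis(study$species)
    vars <- cbind(phen[, .sip_names()], age = ages)
    pmv <- permanova_combined(bc, vars, n_permutations = cfg$permutations,
                              seed = cfg$seed)
    beta <- rbind(pmv$marginal,
                  data.frame(variable = "combined", r2 = pmv$total$r2,
                             pseudo_f = pmv$total$pseudo_f,
                             p_value = pmv$total$p_value))
    emit_df(beta, "beta_permanova.tsv")
    emit_df(diversity_sip_associations(alpha, phen, ages), "alpha_assoc.tsv")
    emit_df(species_sip_association(study$species, phen, ages),
            "species_assoc.tsv")

    ## MGS construction ----------------------------------------------------
    log_line("stage mgs: r>", cfg$correlation_threshold,
             " min_genes=", cfg$min_genes)
    filtered <- filter_genes(study$genes)
    cags <- canopy_cluster(filtered, cfg$correlation_threshold)
    emit_df(cag_assignment(cags), "cags.tsv")
    mgss <- select_mgs(cags, cfg$min_genes)
    mgss <- lapply(mgss, assign_taxonomy, hits = study$gene2taxon,
                   lineage = study$lineage)
    emit_df(do.call(rbind, lapply(mgss, function(g)
      data.frame(mgs_id = g$mgs_id, cag_id = g$cag_id,
                 n_genes = length(g$members), rank = g$taxonomy_rank,
                 label = g$taxonomy_label,
                 classified = g$classified_species))), "mgs.tsv")
    profiles <- do.call(rbind, lapply(mgss, function(g) g$profile))
    rownames(profiles) <- vapply(mgss, function(g) g$mgs_id, "")
    emit_mat(profiles, "mgs_profiles.tsv")

    ## module association --------------------------------------------------
    log_line("stage modules: min_kos=", cfg$min_kos,
             " fdr=", cfg$fdr_threshold)
    ko <- ko_abundance(study$genes, study$gene2ko)
    scc <- ko_sip_scc(ko, phen, ages)
    emit_df(scc, "ko_scc.tsv")
    assoc <- module_sip_test(scc, study$modules, cfg$min_kos,
                             cfg$fdr_threshold)
    emit_df(assoc, "module_assoc.tsv")

    ## driver attribution --------------------------------------------------
    drv_mod <- cfg$driver_module
    drv_sip <- cfg$driver_sip
    if (is.null(drv_mod))
      drv_mod <- if (!is.null(study$truth$target_modules))
        study$truth$target_modules[1] else
          assoc$module_id[which.min(assoc$q_value)]
    if (is.null(drv_sip))
      drv_sip <- if (!is.null(study$truth$target_sip))
        study$truth$target_sip else assoc$sip[which.min(assoc$q_value)]
    log_line("stage drivers: module=", drv_mod, " sip=", drv_sip)
    mgs_assign <- do.call(rbind, lapply(mgss, function(g)
      data.frame(gene_id = g$members, mgs_id = g$mgs_id,
                 stringsAsFactors = FALSE)))
    impacts <- leave_one_mgs_out(
      study$genes, study$gene2ko, mgs_assign,
      study$modules[study$modules$module_id == drv_mod, , drop = FALSE],
      drv_sip, phen, ages)
    emit_df(rank_drivers(impacts), "drivers.tsv")
    log_line("status ok")
    finish()
  }, error = function(e) {
    log_line("status failed: ", conditionMessage(e))
    finish()
    stop(e)
  })
  invisible(result)
}
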