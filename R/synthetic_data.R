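#' Default per-SIP generative trends
#'
#' Intercept, age slope, gender offset (added for males) and residual noise
#' for the ten skin imaging phenotypes (SIPs). Directions follow the known
#' temporal dynamics of facial skin: pigment, pore, UV spot, melanin,
#' hemoglobin and wrinkle scores rise with age; lightening and texture
#' decline; sebum and porphyrins carry no age trend. The default magnitudes
#' (slope 0.35 score-units/year against a residual sd of 10) give marginal
#' age correlations of roughly |r| = 0.3-0.5 at n = 150 — detectable but not
#' trivial.
#'
#' @return A data.frame with columns `sip`, `intercept`, `age_slope`,
#'   `gender_offset`, `noise_sd`.
#' @export
default_sip_trends <- function() {
  data.frame(
    sip = c("lightening", "sebum", "porphyrins", "texture", "melanin",
            "pore", "pigment", "wrinkle", "hemoglobin", "uv_spot"),
    intercept     = c(60, 45, 45, 60, 30, 30, 30, 30, 30, 30),
    age_slope     = c(-0.35, 0, 0, -0.35, 0.35, 0.35, 0.35, 0.35, 0.35, 0.35),
    gender_offset = c(-4, 4, 0, 0, 0, 4, 4, -4, 0, 0),
    noise_sd      = rep(10, 10),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic cohort configuration
#'
#' Parameters of the synthetic metagenome-phenome cohort. Defaults describe
#' the reference study condition used throughout the package's validation:
#' 150 subjects aged 18-65, 40 species carrying 80-120 genes each
#' (~4000 genes), 300 KOs organised into 20 non-overlapping 8-KO modules,
#' and one driver species (the most abundant) that owns >= 90% of the genes
#' of 3 target modules and whose relative abundance is calibrated to a
#' planted Spearman correlation of 0.4 with the pore score.
#'
#' @param n_samples Number of subjects (>= 10).
#' @param age_range Two-element numeric, years.
#' @param female_fraction Proportion of female subjects in \[0, 1\].
#' @param sip_trends Data.frame as [default_sip_trends()].
#' @param n_species Number of species.
#' @param genes_per_species_range Two-element integer range.
#' @param within_species_log_noise_sd Log-scale sd of per-gene multiplicative
#'   noise; the default 0.1 guarantees within-species gene Pearson
#'   correlations > 0.9.
#' @param n_kos Size of the KO universe.
#' @param module_catalog_spec Data.frame with columns `module_id`, `n_kos`;
#'   KOs are allocated to modules without overlap.
#' @param driver_species_id Species that drives the target modules.
#' @param target_modules Module ids whose KO genes are concentrated in the
#'   driver species.
#' @param target_sip SIP name the driver couples to.
#' @param target_correlation Planted Spearman correlation in \[-1, 1\]
#'   between the driver's relative abundance and the target SIP.
#' @param diversity_age_effect Non-negative slope of the concentration
#'   mechanism that makes Shannon diversity rise with age (0 disables).
#' @param species_log_noise_sd Sample-to-sample log-abundance sd per species.
#' @param fraction_unannotated Fraction of genes with no taxonomic hit.
#' @param identity_mean,identity_sd Percent-identity distribution of
#'   taxonomic hits (clipped to \[70, 100\]).
#' @param seed Integer RNG seed; the whole study is a deterministic
#'   function of the configuration.
#' @return An object of class `dermalink_sim_config`.
#' @export
sim_config <- function(n_samples = 150,
                       age_range = c(18, 65),
                       female_fraction = 0.5,
                       sip_trends = default_sip_trends(),
                       n_species = 40,
                       genes_per_species_range = c(80, 120),
                       within_species_log_noise_sd = 0.1,
                       n_kos = 300,
                       module_catalog_spec = data.frame(
                         module_id = sprintf("M%05d", seq_len(20)),
                         n_kos = rep(8L, 20)),
                       driver_species_id = "sp001",
                       target_modules = sprintf("M%05d", 1:3),
                       target_sip = "pore",
                       target_correlation = 0.4,
                       diversity_age_effect = 1,
                       species_log_noise_sd = 0.8,
                       fraction_unannotated = 0.1,
                       identity_mean = 96,
                       identity_sd = 2,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
    female_fraction = female_fraction, sip_trends = sip_trends,
    n_species = as.integer(n_species),
    genes_per_species_range = as.integer(genes_per_species_range),
    within_species_log_noise_sd = within_species_log_noise_sd,
    n_kos = as.integer(n_kos), module_catalog_spec = module_catalog_spec,
    driver_species_id = driver_species_id, target_modules = target_modules,
    target_sip = target_sip, target_correlation = target_correlation,
    diversity_age_effect = diversity_age_effect,
    species_log_noise_sd = species_log_noise_sd,
    fraction_unannotated = fraction_unannotated,
    identity_mean = identity_mean, identity_sd = identity_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "dermalink_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 10)
    stop("n_samples < 10: downstream statistics are undefined on fewer samples")
  if (cfg$n_species < 1 || cfg$n_kos < 1 || any(cfg$genes_per_species_range < 1))
    stop("all counts must be >= 1")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0)
    stop("age_range must be an increasing pair of years")
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1)
    stop("female_fraction must lie in [0, 1]")
  if (abs(cfg$target_correlation) > 1)
    stop("|target_correlation| must be <= 1")
  if (any(cfg$sip_trends$noise_sd < 0) || cfg$within_species_log_noise_sd < 0 ||
      cfg$species_log_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  sips <- default_sip_trends()$sip
  if (!identical(sort(cfg$sip_trends$sip), sort(sips)))
    stop("sip_trends must contain exactly the ten SIPs")
  if (sum(cfg$module_catalog_spec$n_kos) > cfg$n_kos)
    stop("configuration error: module catalog demands more KOs than n_kos")
  if (anyDuplicated(cfg$module_catalog_spec$module_id))
    stop("duplicate module ids in module_catalog_spec")
  if (!all(cfg$target_modules %in% cfg$module_catalog_spec$module_id))
    stop("target_modules must appear in module_catalog_spec")
  if (!cfg$target_sip %in% cfg$sip_trends$sip)
    stop("target_sip must be one of the ten SIPs")
  invisible(cfg)
}

.species_ids <- function(n) sprintf("sp%03d", seq_len(n))

.species_lineage <- function(species_ids) {
  idx <- seq_along(species_ids)
  data.frame(species = species_ids,
             genus = sprintf("gen%03d", ceiling(idx / 2)),
             family = sprintf("fam%03d", ceiling(idx / 4)),
             stringsAsFactors = FALSE)
}

# Species log-abundance model shared by the cohort and the calibration run.
# mu: per-species baseline log-abundance; the age-dependent shrink factor
# compresses the spread so evenness (hence Shannon diversity) rises with age.
.species_logabund <- function(ages, mu, cfg, eps) {
  tnorm <- (ages - cfg$age_range[1]) / diff(cfg$age_range)
  shrink <- 1 / (1 + cfg$diversity_age_effect * tnorm)
  outer(shrink, mu) + cfg$species_log_noise_sd * eps
}

# Calibrate the latent mixing weight so the driver species' relative
# abundance attains the requested Spearman correlation with the target SIP.
# Binary search against a large common-random-numbers simulation; the
# empirical rank correlation is monotone in the weight.
.calibrate_driver_weight <- function(cfg, mu, driver_idx, n_cal = 3000) {
  target <- cfg$target_correlation
  if (target == 0) return(0)
  sgn <- sign(target)
  ages <- stats::runif(n_cal, cfg$age_range[1], cfg$age_range[2])
  male <- stats::runif(n_cal) >= cfg$female_fraction
  tr <- cfg$sip_trends[cfg$sip_trends$sip == cfg$target_sip, ]
  sip <- pmax(0, tr$intercept + tr$age_slope * ages +
                tr$gender_offset * male + stats::rnorm(n_cal, 0, tr$noise_sd))
  z <- as.numeric(scale(sip))
  eps <- matrix(stats::rnorm(n_cal * cfg$n_species), n_cal, cfg$n_species)
  eval_w <- function(w) {
    e <- eps
    e[, driver_idx] <- sgn * w * z + sqrt(1 - w^2) * eps[, driver_idx]
    la <- .species_logabund(ages, mu, cfg, e)
    a <- exp(la)
    rel <- a[, driver_idx] / rowSums(a)
    stats::cor(rank(rel), rank(sip))
  }
  lo <- 0; hi <- 1
  if (sgn * eval_w(1) < sgn * target)
    stop("target_correlation not achievable under this configuration")
  if (sgn * eval_w(0) >= sgn * target) return(0)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (sgn * eval_w(mid) < sgn * target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic metagenome-phenome cohort
#'
#' Draws a complete study — sample metadata, the ten-SIP phenome, species
#' relative abundances, per-gene normalized abundances, gene-to-KO and
#' gene-to-taxon annotations, a module catalog and a lineage table — with
#' every planted effect recorded in the returned `truth` element:
#'
#' * each SIP is an affine function of age and gender plus Gaussian noise,
#'   truncated at 0;
#' * species profiles are log-normal with an age-dependent concentration so
#'   Shannon diversity rises with age when `diversity_age_effect > 0`;
#' * the driver species' log-abundance mixes in a latent standardized copy
#'   of the target SIP, with the mixing weight calibrated by binary search
#'   so its relative abundance attains the planted Spearman correlation;
#' * genes inherit their species' profile times a log-uniform baseline
#'   (2 orders of magnitude) and small multiplicative noise, so
#'   within-species gene pairs are co-abundant (Pearson r > 0.9);
#' * KOs of the target modules are assigned predominantly (>= 90% of their
#'   genes) to the driver species; all other genes draw KOs uniformly from
#'   the remaining universe.
#'
#' The same configuration (including seed) always yields a byte-identical
#' study.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_study`: a list with elements
#'   `metadata`, `phenome`, `species`, `genes` (feature x sample matrices),
#'   `gene2ko`, `gene2taxon`, `modules`, `lineage`, `truth`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  ages <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  male <- stats::runif(n) >= cfg$female_fraction
  gender <- ifelse(male, "male", "female")
  metadata <- data.frame(sample_id = sample_ids, age = ages, gender = gender,
                         stringsAsFactors = FALSE)

  tr <- cfg$sip_trends
  sips <- default_sip_trends()$sip
  phen <- matrix(NA_real_, n, length(sips), dimnames = list(NULL, sips))
  for (s in sips) {
    row <- tr[tr$sip == s, ]
    phen[, s] <- pmax(0, row$intercept + row$age_slope * ages +
                        row$gender_offset * male +
                        stats::rnorm(n, 0, row$noise_sd))
  }
  phenome <- cbind(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
                   as.data.frame(phen))

  ## species profiles -------------------------------------------------------
  species_ids <- .species_ids(cfg$n_species)
  driver_idx <- match(cfg$driver_species_id, species_ids)
  if (is.na(driver_idx)) stop("driver_species_id is not a generated species")
  mu <- seq(2, -2, length.out = cfg$n_species)

  w <- .calibrate_driver_weight(cfg, mu, driver_idx)
  eps <- matrix(stats::rnorm(n * cfg$n_species), n, cfg$n_species)
  if (w > 0) {
    z <- as.numeric(scale(phen[, cfg$target_sip]))
    eps[, driver_idx] <- sign(cfg$target_correlation) * w * z +
      sqrt(1 - w^2) * eps[, driver_idx]
  }
  la <- .species_logabund(ages, mu, cfg, eps)
  ab <- exp(la)
  rel <- ab / rowSums(ab)                      # samples x species
  species <- t(rel)
  dimnames(species) <- list(species_ids, sample_ids)

  ## genes ------------------------------------------------------------------
  ng_per_sp <- sample(seq(cfg$genes_per_species_range[1],
                          cfg$genes_per_species_range[2]),
                      cfg$n_species, replace = TRUE)
  gene_species <- rep(species_ids, ng_per_sp)
  n_genes <- length(gene_species)
  gene_ids <- sprintf("g%06d", seq_len(n_genes))
  baseline <- 10^stats::runif(n_genes, 0, 2)
  noise <- matrix(stats::rnorm(n_genes * n, 0, cfg$within_species_log_noise_sd),
                  n_genes, n)
  genes <- rel[, match(gene_species, species_ids), drop = FALSE]
  genes <- t(genes) * baseline * exp(noise)
  dimnames(genes) <- list(gene_ids, sample_ids)

  ## module catalog and KO assignment --------------------------------------
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  spec <- cfg$module_catalog_spec
  ko_cursor <- 0L
  modules <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    kos <- ko_ids[ko_cursor + seq_len(spec$n_kos[i])]
    ko_cursor <<- ko_cursor + spec$n_kos[i]
    data.frame(module_id = spec$module_id[i], ko_id = kos,
               stringsAsFactors = FALSE)
  }))
  target_kos <- modules$ko_id[modules$module_id %in% cfg$target_modules]
  other_kos <- setdiff(ko_ids, target_kos)

  gene_ko <- character(n_genes)
  is_driver_gene <- gene_species == cfg$driver_species_id
  driver_genes <- which(is_driver_gene)
  # driver genes cover the target-module KOs (round-robin, shuffled)
  gene_ko[driver_genes] <-
    sample(rep(target_kos, length.out = length(driver_genes)))
  # light contamination: ~25% of target KOs also receive one non-driver gene,
  # keeping the driver's share of target-module genes >= 90%
  pool <- which(!is_driver_gene)
  contam_kos <- target_kos[stats::runif(length(target_kos)) < 0.25]
  if (length(contam_kos) > 0) {
    contam_genes <- sample(pool, length(contam_kos))
    gene_ko[contam_genes] <- contam_kos
    pool <- setdiff(pool, contam_genes)
  }
  gene_ko[pool] <- sample(other_kos, length(pool), replace = TRUE)
  gene2ko <- data.frame(gene_id = gene_ids, ko_id = gene_ko,
                        stringsAsFactors = FALSE)

  ## taxonomic annotation ---------------------------------------------------
  annotated <- stats::runif(n_genes) >= cfg$fraction_unannotated
  identity <- pmin(100, pmax(70, stats::rnorm(n_genes, cfg$identity_mean,
                                              cfg$identity_sd)))
  gene2taxon <- data.frame(gene_id = gene_ids[annotated],
                           species = gene_species[annotated],
                           identity_pct = identity[annotated],
                           stringsAsFactors = FALSE)
  lineage <- .species_lineage(species_ids)

  per_species_effect <- stats::setNames(numeric(cfg$n_species), species_ids)
  per_species_effect[cfg$driver_species_id] <- cfg$target_correlation
  truth <- list(
    sip_trends = tr,
    gene_species = stats::setNames(gene_species, gene_ids),
    driver_species_id = cfg$driver_species_id,
    target_modules = cfg$target_modules,
    target_sip = cfg$target_sip,
    target_correlation = cfg$target_correlation,
    driver_mixing_weight = w,
    per_species_sip_effect = per_species_effect,
    diversity_age_effect = cfg$diversity_age_effect,
    seed = cfg$seed
  )

  study <- list(metadata = metadata, phenome = phenome, species = species,
                genes = genes, gene2ko = gene2ko, gene2taxon = gene2taxon,
                modules = modules, lineage = lineage, truth = truth)
  class(study) <- "synthetic_study"
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic metagenome-phenome study\n")
  cat(sprintf("  %d samples, %d species, %d genes, %d KOs in %d modules\n",
              nrow(x$metadata), nrow(x$species), nrow(x$genes),
              length(unique(x$gene2ko$ko_id)),
              length(unique(x$modules$module_id))))
  cat(sprintf("  driver %s -> %s (planted Spearman %.2f)\n",
              x$truth$driver_species_id, x$truth$target_sip,
              x$truth$target_correlation))
  invisible(x)
}
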