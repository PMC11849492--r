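#' Aggregate gene abundances into KO abundances
#'
#' KO abundance per sample is the sum of its member genes' abundances.
#' Genes without a KO annotation are ignored; a gene mapped to more than
#' one KO indicates a malformed catalog and is an error.
#'
#' @param genes Genes x samples abundance matrix.
#' @param gene2ko Data.frame with `gene_id`, `ko_id`.
#' @return KO x samples abundance matrix (KOs with no genes in the table
#'   are absent).
#' @export
ko_abundance <- function(genes, gene2ko) {
  m <- as.matrix(genes)
  ann <- gene2ko[gene2ko$gene_id %in% rownames(m), , drop = FALSE]
  if (anyDuplicated(ann$gene_id) > 0) {
    dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
    stop("malformed catalog: gene(s) mapped to multiple KOs: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (nrow(ann) == 0) return(m[0, , drop = FALSE])
  sub <- m[ann$gene_id, , drop = FALSE]
  out <- rowsum(sub, group = ann$ko_id)
  out[order(rownames(out)), , drop = FALSE]
}

# Vectorized partial Spearman of each matrix row with y, adjusting for z.
# Identical to adjusted_spearman() row by row; rows must be non-constant.
.partial_spearman_rows <- function(mat, y, z) {
  rk <- t(apply(mat, 1, rank))
  ry <- rank(y); rz <- rank(z)
  rxy <- as.numeric(stats::cor(t(rk), ry))
  rxz <- as.numeric(stats::cor(t(rk), rz))
  ryz <- stats::cor(ry, rz)
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pmax(-1, pmin(1, rho))
}

#' Age-adjusted Spearman correlations of every KO with every SIP
#'
#' For each (KO, SIP) pair, the partial Spearman correlation of the KO's
#' abundance with the SIP score, adjusting for age. Constant KOs are
#' dropped with a warning. Set `adjust = FALSE` for plain (unadjusted)
#' Spearman correlations.
#'
#' @param ko_table KO x samples abundance matrix.
#' @param phenome Data.frame with the ten SIP columns, sample-aligned.
#' @param ages Ages in years, sample-aligned.
#' @param adjust Adjust for age (default TRUE).
#' @return Data.frame with `ko`, `sip`, `rho`, `n` (one row per pair).
#' @export
ko_sip_scc <- function(ko_table, phenome, ages, adjust = TRUE) {
  m <- as.matrix(ko_table)
  phen <- .check_phenome(phenome)
  if (ncol(m) != nrow(phen) || length(ages) != nrow(phen))
    stop("inputs are not sample-aligned")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant KO(s) dropped")
    m <- m[sds > 0, , drop = FALSE]
  }
  n <- ncol(m)
  rows <- lapply(.sip_names(), function(s) {
    rho <- if (adjust) .partial_spearman_rows(m, phen[, s], ages)
           else as.numeric(stats::cor(apply(m, 1, rank), rank(phen[, s])))
    data.frame(ko = rownames(m), sip = s, rho = rho, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Module-SIP enrichment test on per-KO rank correlations
#'
#' For each (module, SIP) pair, a two-sided Mann-Whitney U test of the
#' module's KO correlation values against the correlations of all KOs
#' outside the module (for that SIP). q-values are Benjamini-Hochberg over
#' all module x SIP tests jointly; the direction is positive when the
#' in-module median correlation exceeds the out-of-module median.
#'
#' @param scc KO-SIP correlation table from [ko_sip_scc()].
#' @param modules Data.frame with `module_id`, `ko_id` (one pair per row).
#' @param min_kos Minimum in-module KOs present in `scc` (default 3);
#'   smaller modules are skipped with a message.
#' @param fdr_threshold Significance threshold on q (default 0.05).
#' @return Data.frame with `module_id`, `sip`, `median_in`, `median_out`,
#'   `u_statistic`, `p_value`, `q_value`, `direction`, `n_kos_in`,
#'   `significant`.
#' @export
module_sip_test <- function(scc, modules, min_kos = 3, fdr_threshold = 0.05) {
  all_kos <- unique(scc$ko)
  rows <- list()
  for (mod in unique(modules$module_id)) {
    mod_kos <- intersect(modules$ko_id[modules$module_id == mod], all_kos)
    if (length(mod_kos) < min_kos) {
      message("module ", mod, " has fewer than ", min_kos,
              " KOs with correlations; skipped")
      next
    }
    if (length(mod_kos) == length(all_kos))
      stop("module ", mod, " spans the entire KO universe: no background")
    for (s in .sip_names()) {
      sc <- scc[scc$sip == s, , drop = FALSE]
      in_rho <- sc$rho[sc$ko %in% mod_kos]
      out_rho <- sc$rho[!sc$ko %in% mod_kos]
      mw <- mann_whitney_u(in_rho, out_rho)
      rows[[paste(mod, s)]] <- data.frame(
        module_id = mod, sip = s,
        median_in = stats::median(in_rho),
        median_out = stats::median(out_rho),
        u_statistic = mw$u_statistic, p_value = mw$p_value,
        n_kos_in = length(in_rho), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no module passed the min_kos filter")
  out$q_value <- bh_fdr(out$p_value)
  out$direction <- ifelse(out$median_in > out$median_out,
                          "positive", "negative")
  out$significant <- out$q_value < fdr_threshold
  rownames(out) <- NULL
  out
}
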