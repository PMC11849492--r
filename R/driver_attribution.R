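#' Leave-one-MGS-out driver attribution
#'
#' Quantifies each MGS's contribution to a module-SIP correlation: for
#' every candidate MGS, KO abundances of the module's KOs are recomputed
#' after removing the MGS's genes, the age-adjusted Spearman correlation of
#' each KO with the SIP is recomputed, and the impact is the change
#' `delta = median_scc_without - median_scc_full` of the module's median KO
#' correlation. KOs whose abundance becomes all-zero or constant after the
#' removal are dropped from the median (and from `n_kos_retained`); if the
#' module loses all its KOs, `median_scc_without` is NA and the row is
#' flagged rather than erroring.
#'
#' @param genes Genes x samples abundance matrix.
#' @param gene2ko Data.frame with `gene_id`, `ko_id`.
#' @param mgs_assignment Data.frame with `gene_id`, `mgs_id` (or `cag_id`)
#'   mapping genes to MGSs.
#' @param modules Data.frame with `module_id`, `ko_id`; every module in it
#'   is analysed.
#' @param sip Name of the SIP to attribute.
#' @param phenome Data.frame with the ten SIP columns, sample-aligned.
#' @param ages Ages in years, sample-aligned.
#' @param candidate_mgs MGS ids to iterate; default (`NULL`) restricts to
#'   MGSs contributing at least one gene to at least one module KO (any
#'   other MGS has delta = 0 exactly).
#' @return Data.frame with `mgs_id`, `module_id`, `sip`, `median_scc_full`,
#'   `median_scc_without`, `delta`, `n_kos_retained`.
#' @export
leave_one_mgs_out <- function(genes, gene2ko, mgs_assignment, modules, sip,
                              phenome, ages, candidate_mgs = NULL) {
  m <- as.matrix(genes)
  phen <- .check_phenome(phenome)
  if (!sip %in% colnames(phen)) stop("unknown SIP: ", sip)
  sip_scores <- phen[, sip]
  id_col <- if ("mgs_id" %in% names(mgs_assignment)) "mgs_id" else "cag_id"
  gene_mgs <- stats::setNames(mgs_assignment[[id_col]],
                              mgs_assignment$gene_id)
  gene_ko <- stats::setNames(gene2ko$ko_id, gene2ko$gene_id)

  ko_full <- ko_abundance(m, gene2ko)

  median_mod <- function(ko_mat, mod_kos) {
    present <- intersect(mod_kos, rownames(ko_mat))
    if (length(present) == 0)
      return(list(median = NA_real_, retained = 0L))
    sub <- ko_mat[present, , drop = FALSE]
    ok <- apply(sub, 1, stats::sd) > 0
    if (!any(ok)) return(list(median = NA_real_, retained = 0L))
    rho <- .partial_spearman_rows(sub[ok, , drop = FALSE], sip_scores, ages)
    list(median = stats::median(rho), retained = sum(ok))
  }

  rows <- list()
  for (mod in unique(modules$module_id)) {
    mod_kos <- unique(modules$ko_id[modules$module_id == mod])
    full <- median_mod(ko_full, mod_kos)
    mod_genes <- names(gene_ko)[gene_ko %in% mod_kos]
    mod_genes <- intersect(mod_genes, rownames(m))
    contributing <- sort(unique(stats::na.omit(gene_mgs[mod_genes])))
    cands <- if (is.null(candidate_mgs)) contributing else candidate_mgs
    for (cand in cands) {
      removed <- names(gene_mgs)[gene_mgs == cand]
      keep <- setdiff(rownames(m), removed)
      mod_ann <- gene2ko[gene2ko$ko_id %in% mod_kos &
                           gene2ko$gene_id %in% keep, , drop = FALSE]
      ko_wo <- ko_abundance(m[keep, , drop = FALSE], mod_ann)
      wo <- median_mod(ko_wo, mod_kos)
      rows[[paste(mod, cand)]] <- data.frame(
        mgs_id = cand, module_id = mod, sip = sip,
        median_scc_full = full$median,
        median_scc_without = wo$median,
        delta = wo$median - full$median,
        n_kos_retained = wo$retained, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(mgs_id = character(0), module_id = character(0),
                      sip = character(0), median_scc_full = numeric(0),
                      median_scc_without = numeric(0), delta = numeric(0),
                      n_kos_retained = integer(0)))
  rownames(out) <- NULL
  out
}

#' Rank candidate driver MGSs by impact
#'
#' Orders a [leave_one_mgs_out()] table by absolute delta, descending;
#' rows whose post-removal median is undefined (all module KOs lost) sort
#' last; ties break by `mgs_id`.
#'
#' @param impacts Data.frame from [leave_one_mgs_out()].
#' @return The same rows, reordered.
#' @export
rank_drivers <- function(impacts) {
  if (nrow(impacts) == 0) stop("empty impact table")
  undefined <- is.na(impacts$median_scc_without)
  key <- abs(impacts$delta)
  key[undefined] <- -Inf
  impacts[order(-key, impacts$mgs_id), , drop = FALSE]
}
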