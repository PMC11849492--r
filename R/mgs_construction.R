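#' Filter genes by detection prevalence
#'
#' Keeps genes detected (abundance > 0) in at least `min_samples` samples,
#' preserving row order. This is the standard pre-filter before
#' co-abundance clustering.
#'
#' @param genes Genes x samples abundance matrix.
#' @param min_samples Minimum number of samples with non-zero abundance
#'   (default 3).
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_genes <- function(genes, min_samples = 3) {
  m <- as.matrix(genes)
  keep <- rowSums(m > 0) >= min_samples
  if (!any(keep)) message("filter_genes: no genes survive the filter")
  m[keep, , drop = FALSE]
}

#' Canopy clustering of genes into co-abundance gene groups (CAGs)
#'
#' Deterministic greedy canopy clustering: unassigned genes are visited in
#' order of decreasing total abundance; each seed opens a canopy whose
#' membership is the set of unassigned genes with Pearson correlation above
#' `correlation_threshold` to the canopy profile; the profile (per-sample
#' 75th percentile across members) and membership are iterated to a fixed
#' point (at most `max_iterations` rounds); members are then assigned and
#' the walk continues until every gene belongs to exactly one CAG.
#' Constant-profile genes cannot be correlated and become singleton CAGs
#' (with a warning). Output CAGs are sorted by size, descending.
#'
#' @param genes Genes x samples abundance matrix (pre-filtered), >= 3
#'   samples.
#' @param correlation_threshold Pearson correlation radius (default 0.9).
#' @param max_iterations Profile fixed-point iteration cap (default 10).
#' @return A list of CAGs, each a list with `cag_id`, `members` (gene ids)
#'   and `profile` (named per-sample vector).
#' @export
canopy_cluster <- function(genes, correlation_threshold = 0.9,
                           max_iterations = 10) {
  m <- as.matrix(genes)
  if (ncol(m) < 3) stop("need at least 3 samples: correlations are unstable")
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%06d", seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning(sum(constant), " constant-profile gene(s) assigned to singleton CAGs")
  ord <- order(-rowSums(m))
  ord <- ord[!constant[ord]]
  xt <- t(m)  # samples x genes, for vectorized correlation
  assigned <- list()
  remaining <- ord
  while (length(remaining) > 0) {
    seed <- remaining[1]
    profile <- m[seed, ]
    members <- seed
    for (it in seq_len(max_iterations)) {
      if (stats::sd(profile) == 0) break
      r <- suppressWarnings(
        stats::cor(xt[, remaining, drop = FALSE], profile))
      new_members <- remaining[!is.na(r) & r > correlation_threshold]
      if (length(new_members) == 0) { members <- seed; break }
      new_profile <- apply(m[new_members, , drop = FALSE], 2, percentile_75)
      if (identical(sort(new_members), sort(members)) &&
          isTRUE(all.equal(new_profile, profile))) {
        members <- new_members
        break
      }
      members <- new_members
      profile <- new_profile
    }
    assigned[[length(assigned) + 1]] <- members
    remaining <- setdiff(remaining, members)
  }
  for (i in which(constant)) assigned[[length(assigned) + 1]] <- i
  sizes <- lengths(assigned)
  assigned <- assigned[order(-sizes, vapply(assigned, min, 1L))]
  lapply(seq_along(assigned), function(i) {
    ids <- rownames(m)[assigned[[i]]]
    list(cag_id = sprintf("CAG%04d", i), members = ids,
         profile = cag_profile(m, ids))
  })
}

#' Per-sample profile of a CAG
#'
#' The abundance profile of a co-abundance gene group: for each sample, the
#' 75th percentile of the member genes' abundances.
#'
#' @param genes Genes x samples abundance matrix.
#' @param member_ids Gene ids of the group, all present in `genes`.
#' @return Named per-sample numeric vector.
#' @export
cag_profile <- function(genes, member_ids) {
  m <- as.matrix(genes)
  missing <- setdiff(member_ids, rownames(m))
  if (length(missing) > 0)
    stop("unknown gene id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  apply(m[member_ids, , drop = FALSE], 2, percentile_75)
}

#' Promote large CAGs to metagenomic species (MGSs)
#'
#' CAGs containing strictly more than `min_genes` genes are designated
#' MGSs (taxonomy unassigned, rank "unclassified").
#'
#' @param cags CAG list from [canopy_cluster()].
#' @param min_genes Strict lower bound on gene count (default 500; use a
#'   smaller value, e.g. 50, on desk-scale synthetic cohorts).
#' @return A list of MGS objects (`mgs_id`, `cag_id`, `members`, `profile`,
#'   `taxonomy_label`, `taxonomy_rank`, `classified_species`).
#' @export
select_mgs <- function(cags, min_genes = 500) {
  sel <- Filter(function(cg) length(cg$members) > min_genes, cags)
  lapply(seq_along(sel), function(i) {
    cg <- sel[[i]]
    list(mgs_id = sprintf("MGS%03d", i), cag_id = cg$cag_id,
         members = cg$members, profile = cg$profile,
         taxonomy_label = NA_character_, taxonomy_rank = "unclassified",
         classified_species = FALSE)
  })
}

.majority_label <- function(labels) {
  # largest supporting count, ties broken lexicographically
  tab <- sort(table(labels), decreasing = TRUE)
  best <- names(tab)[tab == tab[1]]
  list(label = sort(best)[1], count = unname(tab[1]))
}

#' Assign taxonomy to an MGS by identity-threshold majority rules
#'
#' An MGS is labeled at species, genus or family rank if more than 50% of
#' ALL its member genes (unannotated genes count in the denominator) hit
#' the same taxon with sequence identity of at least 95%, 85% or 75%,
#' respectively, trying ranks in that order. Independently, the MGS is
#' marked a classified species when 80% or more of its member genes are
#' annotated to the same species at the species-level identity convention
#' (>= 95%). Label ties are broken by supporting gene count, then
#' lexicographically.
#'
#' @param mgs An MGS object from [select_mgs()].
#' @param hits Data.frame with `gene_id`, `species`, `identity_pct` (one
#'   best hit per gene; genes may be absent).
#' @param lineage Data.frame with `species`, `genus`, `family` covering
#'   every hit species.
#' @return The MGS with `taxonomy_label`, `taxonomy_rank` and
#'   `classified_species` filled in.
#' @export
assign_taxonomy <- function(mgs, hits, lineage) {
  n <- length(mgs$members)
  h <- hits[hits$gene_id %in% mgs$members, , drop = FALSE]
  missing_lineage <- setdiff(unique(h$species), lineage$species)
  if (length(missing_lineage) > 0)
    stop("lineage table is missing species: ",
         paste(missing_lineage, collapse = ", "))
  h$genus <- lineage$genus[match(h$species, lineage$species)]
  h$family <- lineage$family[match(h$species, lineage$species)]

  rank_rules <- list(
    list(rank = "species", column = "species", min_identity = 95),
    list(rank = "genus",   column = "genus",   min_identity = 85),
    list(rank = "family",  column = "family",  min_identity = 75)
  )
  label <- NA_character_; rank <- "unclassified"
  for (rule in rank_rules) {
    hh <- h[h$identity_pct >= rule$min_identity, , drop = FALSE]
    if (nrow(hh) == 0) next
    mj <- .majority_label(hh[[rule$column]])
    if (mj$count > 0.5 * n) {
      label <- mj$label; rank <- rule$rank
      break
    }
  }
  hs <- h[h$identity_pct >= 95, , drop = FALSE]
  classified <- FALSE
  if (nrow(hs) > 0) {
    mj <- .majority_label(hs$species)
    classified <- mj$count >= 0.8 * n
    if (classified) { label <- mj$label; rank <- "species" }
  }
  mgs$taxonomy_label <- label
  mgs$taxonomy_rank <- rank
  mgs$classified_species <- classified
  mgs
}

#' CAG membership as a gene-to-CAG table
#'
#' @param cags CAG list from [canopy_cluster()].
#' @return Data.frame with columns `gene_id`, `cag_id`.
#' @export
cag_assignment <- function(cags) {
  do.call(rbind, lapply(cags, function(cg)
    data.frame(gene_id = cg$members, cag_id = cg$cag_id,
               stringsAsFactors = FALSE)))
}
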