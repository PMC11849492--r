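# Tab-separated I/O. Numeric cells are printed with %.17g so a write/read
# round trip reproduces doubles bit-exactly.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a feature-by-sample abundance matrix as TSV
#'
#' Features in rows, samples in columns; the first column holds feature ids
#' under the header `feature_id`. Full double precision is preserved.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output file path.
#' @export
write_abundance_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- matrix(.fmt_num(mat), nrow(mat), ncol(mat))
  lines <- c(paste(c("feature_id", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"))
  if (nrow(mat) == 0) lines <- lines[1]
  writeLines(lines, path)
}

#' Read a feature-by-sample abundance matrix from TSV
#'
#' @param path File written by [write_abundance_table()] (first column =
#'   feature ids, remaining columns = samples).
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

.write_tsv_df <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv_df <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a synthetic study to a directory
#'
#' Emits `metadata.tsv`, `phenome.tsv`, `species.tsv`, `genes.tsv`,
#' `gene2ko.tsv`, `gene2taxon.tsv`, `modules.tsv`, `lineage.tsv` and
#' `truth.json`. Reading the directory back with [read_study()] reproduces
#' the in-memory study exactly.
#'
#' @param study A `synthetic_study` object.
#' @param directory Target directory (created if absent).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, directory, overwrite = FALSE) {
  if (!inherits(study, "synthetic_study")) stop("not a synthetic_study")
  if (nrow(study$metadata) == 0) stop("refusing to write a study with no samples")
  if (dir.exists(directory) && length(list.files(directory)) > 0 && !overwrite)
    stop("directory exists and is non-empty; pass overwrite = TRUE")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  .write_tsv_df(study$metadata, p("metadata.tsv"))
  .write_tsv_df(study$phenome, p("phenome.tsv"))
  write_abundance_table(study$species, p("species.tsv"))
  write_abundance_table(study$genes, p("genes.tsv"))
  .write_tsv_df(study$gene2ko, p("gene2ko.tsv"))
  .write_tsv_df(study$gene2taxon, p("gene2taxon.tsv"))
  .write_tsv_df(study$modules, p("modules.tsv"))
  .write_tsv_df(study$lineage, p("lineage.tsv"))
  truth <- study$truth
  truth$gene_species <- as.list(truth$gene_species)
  truth$per_species_sip_effect <- as.list(truth$per_species_sip_effect)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list.files(directory, full.names = TRUE))
}

#' Read a synthetic study back from a directory
#'
#' @param directory Directory written by [write_study()].
#' @return A `synthetic_study` object.
#' @export
read_study <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("metadata.tsv", "phenome.tsv", "species.tsv", "genes.tsv",
              "gene2ko.tsv", "gene2taxon.tsv", "modules.tsv", "lineage.tsv",
              "truth.json"))
    if (!file.exists(p(f))) stop("missing study file: ", f)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth$gene_species <- unlist(truth$gene_species)
  truth$per_species_sip_effect <- unlist(truth$per_species_sip_effect)
  truth$sip_trends <- as.data.frame(truth$sip_trends,
                                    stringsAsFactors = FALSE)
  study <- list(metadata = .read_tsv_df(p("metadata.tsv")),
                phenome = .read_tsv_df(p("phenome.tsv")),
                species = read_abundance_table(p("species.tsv")),
                genes = read_abundance_table(p("genes.tsv")),
                gene2ko = .read_tsv_df(p("gene2ko.tsv")),
                gene2taxon = .read_tsv_df(p("gene2taxon.tsv")),
                modules = .read_tsv_df(p("modules.tsv")),
                lineage = .read_tsv_df(p("lineage.tsv")),
                truth = truth)
  class(study) <- "synthetic_study"
  study
}
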