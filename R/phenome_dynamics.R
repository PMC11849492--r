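.sip_names <- function() default_sip_trends()$sip

.check_phenome <- function(phenome) {
  miss <- setdiff(.sip_names(), names(phenome))
  if (length(miss) > 0)
    stop("phenome table is missing SIP columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(phenome[, .sip_names(), drop = FALSE])
  if (anyNA(m)) stop("phenome table contains missing values")
  if (any(m < 0)) stop("SIP scores must be non-negative")
  m
}

#' Per-SIP age regression with FDR
#'
#' For each of the ten SIPs, fits an ordinary least-squares regression of
#' age on that SIP (the SIP is the independent variable, age the dependent
#' variable) and reports the slope, its two-sided p-value and the
#' Benjamini-Hochberg q-value across the ten tests. Significance is called
#' at q < 0.1. A constant SIP column yields NA for that SIP (with a
#' warning); the other SIPs are still reported.
#'
#' @param phenome Data.frame with the ten SIP columns (and optionally
#'   `sample_id`).
#' @param metadata Data.frame with an `age` column, row-aligned to
#'   `phenome`.
#' @param flip Regress the SIP on age instead (slope of score per year);
#'   default `FALSE` keeps age as the dependent variable.
#' @return Data.frame with columns `sip`, `slope`, `p_value`, `q_value`,
#'   `significant`.
#' @export
sip_age_regression <- function(phenome, metadata, flip = FALSE) {
  m <- .check_phenome(phenome)
  age <- metadata$age
  if (nrow(m) != length(age)) stop("phenome and metadata are not aligned")
  if (nrow(m) < 10) stop("need at least 10 samples")
  res <- lapply(.sip_names(), function(s) {
    x <- m[, s]
    if (stats::sd(x) == 0) {
      warning("SIP column '", s, "' is constant; no regression fitted")
      return(data.frame(sip = s, slope = NA_real_, p_value = NA_real_))
    }
    fit <- if (flip) stats::lm(x ~ age) else stats::lm(age ~ x)
    co <- summary(fit)$coefficients[2, ]
    data.frame(sip = s, slope = unname(co["Estimate"]),
               p_value = unname(co["Pr(>|t|)"]))
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out$significant <- !is.na(out$q_value) & out$q_value < 0.1
  rownames(out) <- NULL
  out
}

#' Principal component analysis of the phenome
#'
#' Z-scores each SIP column (mean 0, sd 1) and eigendecomposes the
#' correlation structure. Component signs are fixed so that each loading
#' vector's largest-magnitude entry is positive, making scores and biplots
#' reproducible.
#'
#' @param phenome Data.frame with the ten SIP columns.
#' @return A list with `scores` (samples x components), `loadings`
#'   (SIPs x components) and `explained_variance` (proportions summing
#'   to 1).
#' @export
phenome_pca <- function(phenome) {
  m <- .check_phenome(phenome)
  if (nrow(m) < 3) stop("need at least 3 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance SIP column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) v[which.max(abs(v))] < 0)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explained_variance = ev)
}

#' Pairwise group separation on a principal component
#'
#' Two-sided Mann-Whitney U tests of a score vector (typically PC1)
#' between every pair of groups, with Benjamini-Hochberg correction across
#' pairs. This is the test behind age-bin and gender separation along PC1.
#'
#' @param scores Numeric vector of component scores.
#' @param groups Factor or character vector of group labels, same length.
#' @return Data.frame with `group1`, `group2`, `u_statistic`, `p_value`,
#'   `q_value`.
#' @export
group_separation_test <- function(scores, groups) {
  groups <- as.factor(groups)
  if (length(scores) != length(groups)) stop("scores and groups differ in length")
  lev <- levels(droplevels(groups))
  if (length(lev) < 2) stop("need at least 2 groups")
  if (any(table(groups)[lev] == 0)) stop("empty group")
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    mw <- mann_whitney_u(scores[groups == pr[1]], scores[groups == pr[2]])
    data.frame(group1 = pr[1], group2 = pr[2],
               u_statistic = mw$u_statistic, p_value = mw$p_value)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
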