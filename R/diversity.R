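#' Shannon diversity per sample
#'
#' Renormalizes each sample (column) to relative abundance and returns
#' H = -sum(p * ln p) over the positive entries, in nats.
#'
#' @param profile Features x samples non-negative matrix.
#' @return Named numeric vector, one value per sample.
#' @export
shannon <- function(profile) {
  m <- as.matrix(profile)
  if (any(m < 0)) stop("abundances must be non-negative")
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  p <- sweep(m, 2, tot, "/")
  apply(p, 2, function(v) { v <- v[v > 0]; -sum(v * log(v)) })
}

#' Bray-Curtis dissimilarity matrix
#'
#' Samples are first renormalized to relative abundance; the dissimilarity
#' between two samples is sum(|x - y|) / sum(x + y) over features.
#'
#' @param profile Features x samples non-negative matrix.
#' @return A symmetric samples x samples matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
bray_curtis <- function(profile) {
  m <- as.matrix(profile)
  if (any(m < 0)) stop("abundances must be non-negative")
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  p <- sweep(m, 2, tot, "/")
  n <- ncol(p)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    xi <- p[, i]
    rest <- (i + 1):n
    num <- colSums(abs(p[, rest, drop = FALSE] - xi))
    den <- colSums(p[, rest, drop = FALSE] + xi)
    d[i, rest] <- d[rest, i] <- num / den
  }
  d
}

.check_dist <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  d
}

# Gower-centered matrix of -0.5 * squared distances
.gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - 1 / n
  j %*% a %*% j
}

.design_matrix <- function(variable) {
  if (is.numeric(variable)) {
    x <- matrix(variable - mean(variable), ncol = 1)
  } else {
    f <- as.factor(variable)
    x <- stats::model.matrix(~f)[, -1, drop = FALSE]
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  x
}

# tr(HGH) = tr(HG) for the idempotent symmetric hat matrix H = QQ'
.tr_hg <- function(G, X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  sum(Q * (G %*% Q))
}

.permanova_fit <- function(G, X, n_permutations, seed) {
  n <- nrow(G)
  q <- qr(X)$rank
  trG <- sum(diag(G))
  trHG <- .tr_hg(G, X)
  r2 <- trHG / trG
  f <- (trHG / q) / ((trG - trHG) / (n - q - 1))
  p <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      Xp <- X[sample.int(n), , drop = FALSE]
      trHGp <- .tr_hg(G, Xp)
      fp <- (trHGp / q) / ((trG - trHGp) / (n - q - 1))
      if (fp >= f) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_permutations)
  }
  list(r2 = r2, pseudo_f = f, p_value = p, q = q)
}

#' PERMANOVA from a distance matrix
#'
#' Permutational multivariate ANOVA in the McArdle-Anderson trace
#' formulation: with G the Gower-centered matrix of -1/2 squared distances
#' and H the hat matrix of the centered design, R2 = tr(HGH)/tr(G) and
#' pseudo-F = (tr(HGH)/q) / (tr((I-H)G(I-H))/(n-q-1)). The p-value is
#' (1 + #permuted F >= observed F) / (1 + n_permutations), permuting the
#' sample labels of the variable.
#'
#' @param dist Symmetric distance matrix (e.g., from [bray_curtis()]).
#' @param variable Numeric or categorical vector, one value per sample.
#' @param n_permutations Number of label permutations (default 9999;
#'   0 skips the permutation test and returns `p_value = NA`).
#' @param seed Integer seed for the permutations.
#' @return A list with `variable`, `r2`, `pseudo_f`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(dist, variable, n_permutations = 9999, seed = 1) {
  d <- .check_dist(dist)
  if (length(variable) != nrow(d)) stop("variable length must match samples")
  if (length(unique(variable)) < 2) stop("zero design variance")
  G <- .gower_center(d)
  X <- .design_matrix(variable)
  fit <- .permanova_fit(G, X, n_permutations, seed)
  list(variable = deparse(substitute(variable)), r2 = fit$r2,
       pseudo_f = fit$pseudo_f, p_value = fit$p_value,
       n_permutations = n_permutations)
}

#' Joint and marginal PERMANOVA over several variables
#'
#' Fits the full design of all variables jointly (the combined fraction of
#' beta-diversity variance they explain) and, separately, a marginal
#' single-variable PERMANOVA per column.
#'
#' @param dist Symmetric distance matrix.
#' @param variables Data.frame of numeric/categorical columns (e.g., the
#'   ten SIPs plus age).
#' @inheritParams permanova
#' @return A list with `total` (joint r2/pseudo_f/p_value) and `marginal`
#'   (data.frame, one row per variable).
#' @export
permanova_combined <- function(dist, variables, n_permutations = 9999,
                               seed = 1) {
  d <- .check_dist(dist)
  if (ncol(variables) < 2) stop("need at least 2 variables")
  if (nrow(variables) != nrow(d)) stop("variables not aligned to samples")
  Xs <- lapply(variables, .design_matrix)
  X <- do.call(cbind, Xs)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    col2var <- rep(seq_along(Xs), vapply(Xs, ncol, 1L))
    bad <- colnames(variables)[unique(col2var[qrx$pivot[-seq_len(qrx$rank)]])]
    stop("collinear (rank-deficient) design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  G <- .gower_center(d)
  total <- .permanova_fit(G, X, n_permutations, seed)
  marginal <- do.call(rbind, lapply(seq_along(Xs), function(i) {
    fit <- .permanova_fit(G, Xs[[i]], n_permutations, seed + i)
    data.frame(variable = colnames(variables)[i], r2 = fit$r2,
               pseudo_f = fit$pseudo_f, p_value = fit$p_value)
  }))
  rownames(marginal) <- NULL
  list(total = list(r2 = total$r2, pseudo_f = total$pseudo_f,
                    p_value = total$p_value),
       marginal = marginal)
}

#' Associations of alpha diversity with age and the SIPs
#'
#' Plain Spearman correlation of the diversity vector with age, and
#' age-adjusted (partial) Spearman correlations with each of the ten SIPs,
#' with Benjamini-Hochberg q-values across the ten SIP tests (significant
#' at q < 0.1).
#'
#' @param diversity Per-sample diversity vector (e.g., from [shannon()]).
#' @param phenome Data.frame with the ten SIP columns, sample-aligned.
#' @param ages Ages in years, sample-aligned.
#' @return Data.frame with `variable`, `rho`, `p_value`, `q_value`,
#'   `significant`; the age row carries `q_value = NA`.
#' @export
diversity_sip_associations <- function(diversity, phenome, ages) {
  m <- .check_phenome(phenome)
  if (length(diversity) != nrow(m) || length(ages) != nrow(m))
    stop("inputs are not sample-aligned")
  age_r <- spearman_rho(diversity, ages)
  rows <- lapply(.sip_names(), function(s) {
    r <- adjusted_spearman(diversity, m[, s], ages)
    data.frame(variable = s, rho = r$rho, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < 0.1
  rbind(data.frame(variable = "age", rho = age_r$rho,
                   p_value = age_r$p_value, q_value = NA_real_,
                   significant = age_r$p_value < 0.05),
        out)
}

#' Per-species SIP associations (covariate-adjusted linear model)
#'
#' A multivariable-association stand-in in the MaAsLin tradition: species
#' relative abundances are arcsine-square-root transformed and regressed on
#' the z-scored SIP with z-scored age as a covariate, per (species, SIP)
#' pair. Species present in fewer than `min_prevalence` of samples are
#' excluded first; q-values are Benjamini-Hochberg over all species x SIP
#' tests jointly.
#'
#' @param species Species x samples relative-abundance matrix.
#' @param phenome Data.frame with the ten SIP columns, sample-aligned.
#' @param ages Ages in years, sample-aligned.
#' @param min_prevalence Minimum fraction of samples with non-zero
#'   abundance (default 0.1).
#' @return Data.frame with `species`, `sip`, `coefficient`, `p_value`,
#'   `q_value`, `significant` (q < 0.1).
#' @export
species_sip_association <- function(species, phenome, ages,
                                    min_prevalence = 0.1) {
  m <- .check_phenome(phenome)
  sp <- as.matrix(species)
  if (ncol(sp) != nrow(m) || length(ages) != nrow(m))
    stop("inputs are not sample-aligned")
  prev <- rowMeans(sp > 0)
  sp <- sp[prev >= min_prevalence, , drop = FALSE]
  zage <- as.numeric(scale(ages))
  rows <- list()
  for (spec in rownames(sp)) {
    y <- asin(sqrt(pmin(1, sp[spec, ])))
    if (stats::sd(y) == 0) {
      warning("species '", spec, "' has zero variance after filtering; skipped")
      next
    }
    for (s in .sip_names()) {
      zs <- as.numeric(scale(m[, s]))
      fit <- stats::lm(y ~ zs + zage)
      co <- summary(fit)$coefficients
      rows[[paste(spec, s)]] <- data.frame(
        species = spec, sip = s,
        coefficient = co["zs", "Estimate"],
        p_value = co["zs", "Pr(>|t|)"])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(species = character(0), sip = character(0),
                                      coefficient = numeric(0),
                                      p_value = numeric(0),
                                      q_value = numeric(0),
                                      significant = logical(0)))
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < 0.1
  rownames(out) <- NULL
  out
}
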