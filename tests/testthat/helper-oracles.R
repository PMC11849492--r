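# Independent oracle implementations used to cross-check the package's
# statistics, written directly from the textbook definitions.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (tie-free inputs only).
oracle_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force Benjamini-Hochberg step-up q-values from the definition:
# q_i = min over thresholds t >= p_i of m * t / #{p <= t}.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(m * cand / vapply(cand, function(t) sum(p <= t), 1)))
  }, 1)
}

# Textbook Shannon entropy of one abundance vector (nats).
oracle_shannon <- function(x) {
  p <- x / sum(x); p <- p[p > 0]
  -sum(p * log(p))
}

# Textbook Bray-Curtis dissimilarity of two relative-abundance vectors.
oracle_bray_curtis <- function(x, y) {
  x <- x / sum(x); y <- y / sum(y)
  sum(abs(x - y)) / sum(x + y)
}

# PERMANOVA pseudo-F over all label permutations of a small sample set;
# returns the exact permutation p (observed included among permutations).
oracle_permanova_exact_p <- function(d, groups) {
  n <- length(groups)
  perms <- .permutations(n)
  f_for <- function(g) {
    fit <- permanova(d, g, n_permutations = 0)
    fit$pseudo_f
  }
  f_obs <- f_for(groups)
  fs <- apply(perms, 1, function(idx) f_for(groups[idx]))
  mean(fs >= f_obs)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Small synthetic configuration used where full-scale cohorts are not needed.
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    n_samples = 60, n_species = 12, genes_per_species_range = c(25, 35),
    n_kos = 60,
    module_catalog_spec = data.frame(module_id = sprintf("M%05d", 1:8),
                                     n_kos = rep(6L, 8)),
    target_modules = sprintf("M%05d", 1:2),
    seed = seed, ...
  )
}
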