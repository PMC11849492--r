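test_that("shannon matches closed forms and the vegan oracle", {
  m <- cbind(u = rep(1, 4), s = c(5, 0, 0, 0), p = c(0.5, 0.25, 0.25, 0))
  h <- shannon(m)
  expect_equal(unname(h["u"]), log(4), tolerance = 1e-9)
  expect_equal(unname(h["s"]), 0)
  expect_equal(unname(h["p"]), 1.039721, tolerance = 1e-6)
  expect_error(shannon(cbind(a = c(1, 1), b = c(0, 0))), "b")

  set.seed(1)
  prof <- matrix(rexp(30 * 100), 30, 100)
  colnames(prof) <- paste0("s", 1:100)
  mine <- shannon(prof)
  expect_equal(unname(mine), unname(apply(prof, 2, oracle_shannon)),
               tolerance = 1e-12)
  expect_equal(unname(mine),
               unname(vegan::diversity(t(prof), index = "shannon")),
               tolerance = 1e-12)
})

test_that("bray_curtis matches closed forms and the vegan oracle", {
  m <- cbind(a = c(0.6, 0.4), b = c(0.2, 0.8), c = c(0.6, 0.4))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.4, tolerance = 1e-9)
  expect_equal(d["a", "c"], 0)
  disj <- bray_curtis(cbind(a = c(1, 0), b = c(0, 3)))
  expect_equal(disj["a", "b"], 1)

  set.seed(2)
  prof <- matrix(rexp(25 * 40), 25, 40, dimnames = list(NULL, paste0("s", 1:40)))
  mine <- bray_curtis(prof)
  rel <- t(prof) / colSums(prof)
  ora <- as.matrix(vegan::vegdist(rel, method = "bray"))
  expect_equal(unname(mine), unname(ora), tolerance = 1e-12)
  for (i in 1:5) for (j in 1:5)
    expect_equal(mine[i, j], oracle_bray_curtis(prof[, i], prof[, j]),
                 tolerance = 1e-12)
})

test_that("permanova solves the two-cluster fixture exactly", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0
  g <- c("a", "a", "b", "b")
  fit <- permanova(d, g, n_permutations = 9999, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # enumeration oracle: 3 distinct splits, 1 maximal
  expect_equal(oracle_permanova_exact_p(d, g), 1 / 3, tolerance = 1e-12)
  expect_lt(abs(fit$p_value - 1 / 3), 0.03)
  expect_error(permanova(d, rep("a", 4)), "zero design variance")
  expect_error(permanova(d + upper.tri(d) * 0.5, g), "symmetric")
})

test_that("permanova agrees with vegan::adonis2 on random data", {
  set.seed(3)
  prof <- matrix(rexp(20 * 30), 20, 30, dimnames = list(NULL, paste0("s", 1:30)))
  d <- bray_curtis(prof)
  x <- rnorm(30)
  mine <- permanova(d, x, n_permutations = 0)
  ref <- vegan::adonis2(as.dist(d) ~ x, permutations = 2)
  expect_equal(mine$r2, ref$R2[1], tolerance = 1e-8)
  expect_equal(mine$pseudo_f, ref$F[1], tolerance = 1e-8)
  g <- rep(c("u", "v", "w"), length.out = 30)
  mine2 <- permanova(d, g, n_permutations = 0)
  ref2 <- vegan::adonis2(as.dist(d) ~ g, permutations = 2)
  expect_equal(mine2$r2, ref2$R2[1], tolerance = 1e-8)
  expect_equal(mine2$pseudo_f, ref2$F[1], tolerance = 1e-8)
})

test_that("permanova R2 on a two-level factor equals 1 - SSW/SST", {
  set.seed(4)
  prof <- matrix(rexp(15 * 24), 15, 24, dimnames = list(NULL, paste0("s", 1:24)))
  d <- bray_curtis(prof)
  g <- rep(c("a", "b"), each = 12)
  n <- 24
  sst <- sum(d[upper.tri(d)]^2) / n
  ssw <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    dd <- d[idx, idx]
    ssw <- ssw + sum(dd[upper.tri(dd)]^2) / length(idx)
  }
  expect_equal(permanova(d, g, n_permutations = 0)$r2, 1 - ssw / sst,
               tolerance = 1e-10)
})

test_that("permanova is invariant to joint permutation and to sample duplication", {
  set.seed(5)
  prof <- matrix(rexp(12 * 20), 12, 20, dimnames = list(NULL, paste0("s", 1:20)))
  d <- bray_curtis(prof)
  x <- rnorm(20)
  base <- permanova(d, x, n_permutations = 499, seed = 7)
  perm <- sample(20)
  joint <- permanova(d[perm, perm], x[perm], n_permutations = 499, seed = 7)
  expect_equal(base$r2, joint$r2, tolerance = 1e-12)
  expect_equal(base$p_value, joint$p_value, tolerance = 0.05)
  idx <- rep(seq_len(20), 2)
  dup <- permanova(d[idx, idx], x[idx], n_permutations = 0)
  expect_equal(dup$r2, base$r2, tolerance = 1e-12)
})

test_that("permanova_combined reports joint and marginal structure", {
  set.seed(6)
  # two clusters with disjoint feature support, fully explained by one
  # binary variable
  prof <- rbind(cbind(matrix(rexp(10 * 15), 10, 15), matrix(0, 10, 15)),
                cbind(matrix(0, 10, 15), matrix(rexp(10 * 15), 10, 15)))
  colnames(prof) <- paste0("s", 1:30)
  d <- bray_curtis(prof)
  vars <- data.frame(cluster = rep(c(0, 1), each = 15), noise = rnorm(30))
  fit <- permanova_combined(d, vars, n_permutations = 0)
  marg <- fit$marginal$r2[fit$marginal$variable == "cluster"]
  expect_gt(marg, 0.5)
  # the joint fit adds only the noise column's ~1/(n-1) share
  expect_lt(abs(fit$total$r2 - marg), 0.06)
  vars$dup <- vars$cluster
  expect_error(permanova_combined(d, vars, n_permutations = 0), "collinear")
  expect_error(permanova_combined(d, vars["cluster"], 0), "at least 2")
})

test_that("joint null R2 sits near its q/(n-1) expectation", {
  r2s <- vapply(1:20, function(seed) {
    set.seed(seed + 40)
    prof <- matrix(rexp(25 * 200), 25, 200,
                   dimnames = list(NULL, paste0("s", 1:200)))
    d <- bray_curtis(prof)
    vars <- as.data.frame(matrix(rnorm(200 * 11), 200, 11))
    permanova_combined(d, vars, n_permutations = 0)$total$r2
  }, 1)
  expected <- 11 / 199
  expect_lt(abs(mean(r2s) - expected), 0.5 * expected)
})

test_that("diversity_sip_associations separates age signal from SIP noise", {
  flagged <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 150
    age <- runif(n, 18, 65)
    div <- age / 10 + rnorm(n, 0, 0.5)       # monotone in age
    phen <- as.data.frame(matrix(abs(rnorm(n * 10, 50, 10)), n, 10,
                                 dimnames = list(NULL, default_sip_trends()$sip)))
    res <- diversity_sip_associations(div, phen, age)
    expect_gt(res$rho[res$variable == "age"], 0.8)
    sum(res$significant[res$variable != "age"])
  }, 1)
  expect_gte(sum(flagged == 0), 18)
  phen2 <- as.data.frame(matrix(c(1, 2), 2, 10,
                                dimnames = list(NULL, default_sip_trends()$sip)))
  expect_error(diversity_sip_associations(c(1, 2), phen2, c(30, 40)),
               "at least")
})

test_that("species_sip_association recovers a planted negative sebum coupling", {
  set.seed(9)
  n <- 150
  age <- runif(n, 18, 65)
  phen <- as.data.frame(matrix(abs(rnorm(n * 10, 50, 10)), n, 10,
                               dimnames = list(NULL, default_sip_trends()$sip)))
  sp <- matrix(abs(rnorm(20 * n, 0.05, 0.01)), 20, n,
               dimnames = list(paste0("sp", 1:20), paste0("S", 1:n)))
  sp[1, ] <- pmax(0.001, 0.2 - 0.002 * phen$sebum + rnorm(n, 0, 0.01))
  sp <- sweep(sp, 2, colSums(sp), "/")
  res <- species_sip_association(sp, phen, age)
  hit <- res[res$species == "sp1" & res$sip == "sebum", ]
  expect_lt(hit$coefficient, 0)
  expect_lt(hit$q_value, 0.1)

  # prevalence filter removes an absent species
  sp2 <- rbind(sp, ghost = 0)
  res2 <- species_sip_association(sp2, phen, age)
  expect_false("ghost" %in% res2$species)
})

test_that("species_sip_association is calibrated on shuffled abundances", {
  set.seed(10)
  n <- 150
  age <- runif(n, 18, 65)
  phen <- as.data.frame(matrix(abs(rnorm(n * 10, 50, 10)), n, 10,
                               dimnames = list(NULL, default_sip_trends()$sip)))
  sp <- matrix(rexp(40 * n), 40, n, dimnames = list(paste0("sp", 1:40), NULL))
  sp <- sweep(sp, 2, colSums(sp), "/")
  res <- species_sip_association(sp, phen, age)
  expect_lte(mean(res$q_value < 0.1), 0.1)
})
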