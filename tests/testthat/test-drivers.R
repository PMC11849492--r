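# Deterministic fixture: 4 module KOs, each fed by one gene of MGS "X"
# carrying a planted SIP signal and one gene of MGS "Y" carrying noise;
# `share` sets X's fraction of each KO's abundance.
make_driver_fixture <- function(share, n = 120, seed = 1) {
  set.seed(seed)
  age <- runif(n, 18, 65)
  phen <- as.data.frame(matrix(abs(rnorm(n * 10, 50, 10)), n, 10,
                               dimnames = list(NULL, default_sip_trends()$sip)))
  signal <- scale(phen$pore)[, 1]
  genes <- do.call(rbind, lapply(1:4, function(k) {
    gx <- share * exp(0.8 * signal + rnorm(n, 0, 0.2))
    gy <- (1 - share) * exp(rnorm(n, 0, 0.5))
    rbind(gx, gy)
  }))
  rownames(genes) <- paste0("g", 1:8)
  colnames(genes) <- paste0("S", 1:n)
  list(genes = genes, phen = phen, age = age,
       gene2ko = data.frame(gene_id = paste0("g", 1:8),
                            ko_id = rep(sprintf("K%05d", 1:4), each = 2)),
       assignment = data.frame(gene_id = paste0("g", 1:8),
                               mgs_id = rep(c("X", "Y"), 4)),
       modules = data.frame(module_id = "M1",
                            ko_id = sprintf("K%05d", 1:4)))
}

test_that("non-contributing MGSs have exactly zero impact; sole contributors flag NA", {
  fx <- make_driver_fixture(0.7)
  asg <- rbind(fx$assignment,
               data.frame(gene_id = "g9", mgs_id = "Z"))
  genes <- rbind(fx$genes, g9 = rexp(ncol(fx$genes)))
  imp <- leave_one_mgs_out(genes, fx$gene2ko, asg, fx$modules, "pore",
                           fx$phen, fx$age, candidate_mgs = c("X", "Y", "Z"))
  expect_identical(imp$delta[imp$mgs_id == "Z"], 0)  # no module genes at all
  expect_equal(imp$n_kos_retained[imp$mgs_id == "X"], 4)

  # an MGS owning every module gene leaves nothing behind
  solo <- fx$assignment
  solo$mgs_id <- "X"
  imp2 <- leave_one_mgs_out(fx$genes, fx$gene2ko, solo, fx$modules, "pore",
                            fx$phen, fx$age)
  expect_equal(imp2$n_kos_retained, 0)
  expect_true(is.na(imp2$median_scc_without))
})

test_that("sequential removal equals joint removal (KO abundances are sums)", {
  fx <- make_driver_fixture(0.5)
  set.seed(9)
  extra <- matrix(rexp(4 * ncol(fx$genes)), 4, ncol(fx$genes),
                  dimnames = list(paste0("z", 1:4), colnames(fx$genes)))
  genes <- rbind(fx$genes, extra)
  gene2ko <- rbind(fx$gene2ko,
                   data.frame(gene_id = paste0("z", 1:4),
                              ko_id = sprintf("K%05d", 1:4)))
  asg <- rbind(fx$assignment,
               data.frame(gene_id = paste0("z", 1:4), mgs_id = "Z"))
  # joint removal of X and Y as one merged pseudo-MGS
  merged <- asg
  merged$mgs_id[merged$mgs_id %in% c("X", "Y")] <- "XY"
  joint <- leave_one_mgs_out(genes, gene2ko, merged, fx$modules,
                             "pore", fx$phen, fx$age, candidate_mgs = "XY")
  # sequential: drop X's genes from the table, then remove Y
  keep <- setdiff(rownames(genes), asg$gene_id[asg$mgs_id == "X"])
  seq2 <- leave_one_mgs_out(genes[keep, ], gene2ko,
                            asg[asg$mgs_id != "X", ],
                            fx$modules, "pore", fx$phen, fx$age,
                            candidate_mgs = "Y")
  expect_equal(joint$median_scc_without, seq2$median_scc_without)
  expect_equal(joint$n_kos_retained, seq2$n_kos_retained)
  expect_equal(joint$n_kos_retained, 4)
})

test_that("impact shrinks monotonically with the MGS's abundance share", {
  deltas <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(share) {
    fx <- make_driver_fixture(share, seed = 42)
    imp <- leave_one_mgs_out(fx$genes, fx$gene2ko, fx$assignment,
                             fx$modules, "pore", fx$phen, fx$age,
                             candidate_mgs = "X")
    abs(imp$delta)
  }, 1)
  expect_true(all(diff(deltas) < 0))
})

test_that("the planted driver MGS produces the dominant, sign-opposed impact", {
  st <- generate_cohort(sim_config(seed = 17))
  cags <- canopy_cluster(filter_genes(st$genes))
  mgss <- select_mgs(cags, 50)
  asg <- do.call(rbind, lapply(mgss, function(g)
    data.frame(gene_id = g$members, mgs_id = g$mgs_id)))
  imp <- leave_one_mgs_out(
    st$genes, st$gene2ko, asg,
    st$modules[st$modules$module_id %in% st$truth$target_modules, ],
    st$truth$target_sip, st$phenome, st$metadata$age)
  ranked <- rank_drivers(imp)
  drv_genes <- names(st$truth$gene_species)[
    st$truth$gene_species == st$truth$driver_species_id]
  driver_mgs <- names(which.max(table(asg$mgs_id[asg$gene_id %in% drv_genes])))
  expect_identical(ranked$mgs_id[1], driver_mgs)
  expect_lt(ranked$delta[1] * sign(st$truth$target_correlation), 0)
})

test_that("rank_drivers orders by |delta| with undefined rows last", {
  tab <- data.frame(mgs_id = c("A", "B", "C", "D"),
                    module_id = "M1", sip = "pore",
                    median_scc_full = 0.4,
                    median_scc_without = c(0.76, 0.35, 0.4, NA),
                    delta = c(0.36, -0.05, 0, NA),
                    n_kos_retained = c(4, 4, 4, 0))
  ranked <- rank_drivers(tab)
  expect_identical(ranked$mgs_id, c("A", "B", "C", "D"))
  # permutation invariance
  expect_identical(rank_drivers(tab[c(3, 1, 4, 2), ])$mgs_id,
                   c("A", "B", "C", "D"))
  expect_identical(rank_drivers(tab[2, ])$mgs_id, "B")
  expect_error(rank_drivers(tab[0, ]), "empty")
})
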