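test_that("filter_genes applies the detection rule at the boundary", {
  m <- rbind(two = c(1, 2, 0, 0), three = c(1, 2, 3, 0), all = c(1, 1, 1, 1))
  colnames(m) <- paste0("S", 1:4)
  kept <- filter_genes(m, min_samples = 3)
  expect_setequal(rownames(kept), c("three", "all"))
  expect_identical(filter_genes(m, min_samples = 0), m)
})

test_that("canopy clustering separates exact co-abundance from anti-correlation", {
  prof <- c(5, 1, 4, 2, 6)
  m <- rbind(g1 = prof, g2 = 2 * prof, g3 = prof + 0.001,
             g4 = rev(prof) * 3)
  colnames(m) <- paste0("S", 1:5)
  cags <- canopy_cluster(m)
  expect_length(cags, 2)
  expect_setequal(cags[[1]]$members, c("g1", "g2", "g3"))
  expect_setequal(cags[[2]]$members, "g4")
  # determinism
  expect_identical(canopy_cluster(m), cags)
  expect_error(canopy_cluster(m[, 1:2]), "3 samples")
  mc <- rbind(m, flat = rep(2, 5))
  expect_warning(cags2 <- canopy_cluster(mc), "constant")
  expect_true(any(vapply(cags2, function(cg) identical(cg$members, "flat"), TRUE)))
})

test_that("every filtered gene lands in exactly one CAG", {
  st <- generate_cohort(small_sim_config(seed = 3))
  filtered <- filter_genes(st$genes)
  cags <- canopy_cluster(filtered)
  members <- unlist(lapply(cags, `[[`, "members"))
  expect_setequal(members, rownames(filtered))
  expect_equal(anyDuplicated(members), 0)
  # members correlate with their final profile above the threshold
  for (cg in cags[1:3]) {
    if (length(cg$members) < 2) next
    r <- cor(t(filtered[cg$members, , drop = FALSE]), cg$profile)
    expect_true(all(r > 0.9))
  }
})

test_that("canopy clustering reassembles species from the default cohort", {
  st <- generate_cohort(sim_config(seed = 13))
  cags <- canopy_cluster(filter_genes(st$genes))
  asg <- cag_assignment(cags)
  truth <- st$truth$gene_species[asg$gene_id]
  for (sp in unique(truth)) {
    cag_of_sp <- asg$cag_id[truth == sp]
    expect_gte(max(table(cag_of_sp)) / length(cag_of_sp), 0.95)
  }
})

test_that("raising the correlation threshold never grows the largest CAG", {
  set.seed(14)
  m <- matrix(rexp(60 * 20), 60, 20)
  m <- m * rep(rexp(60, 0.2), 20)  # correlated blocks via row scaling
  rownames(m) <- paste0("g", 1:60); colnames(m) <- paste0("S", 1:20)
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th) {
    max(lengths(lapply(canopy_cluster(m, correlation_threshold = th),
                       `[[`, "members")))
  }, 1)
  expect_true(all(diff(sizes) <= 0))
})

test_that("cag_profile is the per-sample 75th percentile of members", {
  m <- rbind(a = c(1, 10), b = c(2, 20), c = c(3, 30), d = c(4, 40))
  colnames(m) <- c("S1", "S2")
  expect_equal(cag_profile(m, c("a", "b", "c", "d")),
               c(S1 = 3.25, S2 = 32.5))
  expect_equal(cag_profile(m, "b"), m["b", ])
  mz <- rbind(a = c(0, 1), b = c(0, 2), c = c(0, 3))
  colnames(mz) <- c("S1", "S2")
  expect_equal(unname(cag_profile(mz, c("a", "b", "c"))[1]), 0)
  expect_error(cag_profile(m, "nope"), "unknown gene")
})

test_that("select_mgs applies the strict gene-count rule", {
  fake_cag <- function(id, n) list(cag_id = id,
                                   members = paste0(id, "_", seq_len(n)),
                                   profile = c(S1 = 1))
  cags <- list(fake_cag("CAG0001", 501), fake_cag("CAG0002", 500),
               fake_cag("CAG0003", 3))
  sel <- select_mgs(cags, min_genes = 500)
  expect_length(sel, 1)
  expect_identical(sel[[1]]$cag_id, "CAG0001")
  expect_identical(sel[[1]]$taxonomy_rank, "unclassified")
  expect_length(select_mgs(cags, min_genes = 0), 3)
})

make_mgs <- function(n) list(mgs_id = "MGS001", cag_id = "CAG0001",
                             members = paste0("g", seq_len(n)),
                             profile = c(S1 = 1),
                             taxonomy_label = NA_character_,
                             taxonomy_rank = "unclassified",
                             classified_species = FALSE)

lineage_tab <- data.frame(species = c("A", "B"), genus = c("G", "G"),
                          family = c("F", "F"))

test_that("taxonomy rules classify species at the 50% and 80% thresholds", {
  mgs <- make_mgs(100)
  # 85% of genes hit species A at 96% identity -> classified species
  hits <- data.frame(gene_id = paste0("g", 1:85), species = "A",
                     identity_pct = 96)
  out <- assign_taxonomy(mgs, hits, lineage_tab)
  expect_identical(out$taxonomy_rank, "species")
  expect_identical(out$taxonomy_label, "A")
  expect_true(out$classified_species)

  # 55% -> species rank but not a classified species
  out2 <- assign_taxonomy(mgs, hits[1:55, ], lineage_tab)
  expect_identical(out2$taxonomy_rank, "species")
  expect_false(out2$classified_species)

  # 40% A + 20% B (same genus) at 88% -> genus fallback (60% > 50%)
  hits3 <- data.frame(gene_id = paste0("g", 1:60),
                      species = rep(c("A", "B"), c(40, 20)),
                      identity_pct = 88)
  out3 <- assign_taxonomy(mgs, hits3, lineage_tab)
  expect_identical(out3$taxonomy_rank, "genus")
  expect_identical(out3$taxonomy_label, "G")
  expect_false(out3$classified_species)
})

test_that("taxonomy ties break by count then lexicographically, and lineage is mandatory", {
  mgs <- make_mgs(10)
  hits <- data.frame(gene_id = paste0("g", 1:8),
                     species = rep(c("B", "A"), each = 4),
                     identity_pct = 97)
  out <- assign_taxonomy(mgs, hits, lineage_tab)
  # species-level majority fails (4/10 each), genus G covers 8/10
  expect_identical(out$taxonomy_rank, "genus")
  expect_identical(out$taxonomy_label, "G")

  bad <- data.frame(gene_id = "g1", species = "Z", identity_pct = 99)
  expect_error(assign_taxonomy(mgs, bad, lineage_tab), "Z")
})
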