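test_that("random trees have the right shape and are seed-deterministic", {
  t2 <- generate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_true(ape::is.rooted(t2))

  t800 <- generate_tree(800, seed = 1)
  expect_equal(length(t800$tip.label), 800)
  expect_equal(t800$Nnode, 799)           # fully bifurcating rooted tree
  expect_true(all(t800$edge.length >= 0))

  expect_identical(ape::write.tree(generate_tree(50, seed = 9)),
                   ape::write.tree(generate_tree(50, seed = 9)))
  expect_false(identical(ape::write.tree(generate_tree(50, seed = 9)),
                         ape::write.tree(generate_tree(50, seed = 10))))
  expect_error(generate_tree(1), "at least 2")
})

test_that("synthetic taxonomy spans the required phyla with nested lineages", {
  tax <- generate_taxonomy(800, seed = 2)
  expect_equal(nrow(tax), 800)
  expect_gte(length(unique(tax$phylum)), 6)
  expect_true(all(c("Bacteroidetes", "Verrucomicrobia", "Firmicutes",
                    "Proteobacteria") %in% tax$phylum))
  # deeper ranks refine shallower ones
  expect_true(all(startsWith(tax$genus, tax$family)))
  expect_true(all(startsWith(tax$family, tax$order)))
})

test_that("donor communities are heavy-tailed with subject-specific masks", {
  cfg <- synthetic_config()
  top_decile_share <- vapply(1:100, function(s) {
    a <- generate_donor_community(cfg, 1, seed = s)
    expect_equal(sum(a), 1)
    sum(sort(a, decreasing = TRUE)[1:80])
  }, 0)
  expect_gt(mean(top_decile_share > 0.5), 0.95)

  a1 <- generate_donor_community(cfg, 1, seed = 1)
  a2 <- generate_donor_community(cfg, 2, seed = 2)
  shared <- sum(a1 > 0 & a2 > 0) / sum(a1 > 0 | a2 > 0)
  expect_lt(shared, 1)
})

test_that("aliquot sampling is multinomial at the requested depth", {
  donor <- c(a = 0.5, b = 0.3, c = 0.2)
  x <- sample_aliquot(donor, 60000, seed = 1)
  expect_equal(sum(x), 60000)
  expect_lt(abs(x[["a"]] - 30000), 4 * sqrt(60000 * 0.25))

  expect_identical(sample_aliquot(donor, 1000, seed = 3),
                   sample_aliquot(donor, 1000, seed = 3))

  # overdispersion inflates variance beyond multinomial
  set.seed(1)
  plain <- vapply(1:200, function(s) sample_aliquot(donor, 1000, s)[["a"]], 0)
  od <- vapply(1:200, function(s)
    sample_aliquot(donor, 1000, s + 1000, overdispersion = 0.05)[["a"]], 0)
  expect_gt(var(od), var(plain))
})

test_that("paired aliquots of one donor recover nearly all included OTUs", {
  cfg <- synthetic_config()
  donor <- generate_donor_community(cfg, 1, seed = 21)
  s1 <- sample_aliquot(donor, 60000, seed = 22)
  s2 <- sample_aliquot(donor, 60000, seed = 23)
  rec <- taxa_recovery(s1, s2, tau = 0.001)
  expect_gt(rec$recovery_pct, 99)
  expect_gt(abundance_captured(s1, s2), 98)
})

test_that("engraftment has exact identity and extinction limits", {
  cfg <- synthetic_config(retention_p = 1,
                          phylum_fold_changes = setNames(numeric(0), character(0)),
                          engraft_noise_sigma = 0)
  tax <- generate_taxonomy(cfg$n_otus, seed = 1)
  donor <- generate_donor_community(cfg, 1, seed = 2)
  eng <- simulate_engraftment(donor, tax, cfg, seed = 3)
  for (m in seq_len(ncol(eng$props)))
    expect_equal(unname(eng$props[, m]), unname(donor))

  cfg0 <- synthetic_config(retention_p = 0)
  eng0 <- simulate_engraftment(donor, tax, cfg0, seed = 3)
  expect_true(all(eng0$props == 0))
  expect_false(any(eng0$retained))
  # downstream recovery of an extinct community is 0%
  s2 <- sample_aliquot(donor, 10000, seed = 4)
  mice <- matrix(0L, length(donor), 3)
  expect_equal(taxa_recovery(s2, mice)$recovery_pct, 0)
})

test_that("engraftment losses concentrate in low-abundance taxa", {
  cfg <- synthetic_config()
  tax <- generate_taxonomy(cfg$n_otus, seed = 1)
  set.seed(31)
  lost <- c(); kept <- c()
  for (s in 1:10) {
    donor <- generate_donor_community(cfg, s, seed = 100 + s)
    eng <- simulate_engraftment(donor, tax, cfg, seed = 200 + s)
    incl <- donor >= cfg$tau
    lost <- c(lost, donor[incl & !eng$retained])
    kept <- c(kept, donor[incl & eng$retained])
  }
  expect_lt(median(lost), median(kept))
  # typical losses sit in the 0.1-0.3% relative abundance band
  expect_true(median(lost) >= 0.001 && median(lost) <= 0.003)
})

test_that("phylum fold changes shift mouse communities in the reported directions", {
  st <- default_study()
  ph <- aggregate_by_rank(st$counts, st$tax, "phylum")
  prop <- sweep(ph, 2, colSums(ph), "/")
  man <- st$manifest
  up <- 0; down <- 0; n_up <- 0; n_down <- 0
  for (sid in unique(man$subject_id)) {
    s2 <- prop[, man$sample_id[man$subject_id == sid & man$role == "S2"]]
    mice <- rowMeans(prop[, man$sample_id[man$subject_id == sid &
                                            man$role == "mouse"], drop = FALSE])
    if (s2["Bacteroidetes"] > 0) { n_up <- n_up + 1
      up <- up + (mice["Bacteroidetes"] > s2["Bacteroidetes"]) }
    if (s2["Firmicutes"] > 0) { n_down <- n_down + 1
      down <- down + (mice["Firmicutes"] < s2["Firmicutes"]) }
  }
  # sign test: blooms/contractions in the stated directions
  expect_lt(binom.test(up, n_up, 0.5, alternative = "greater")$p.value, 0.01)
  expect_lt(binom.test(down, n_down, 0.5, alternative = "greater")$p.value, 0.01)
})

test_that("phenotypes encode the inverse TMAO-choline relationship", {
  cfg <- synthetic_config()
  man <- data.frame(sample_id = sprintf("s%d_M%d", rep(1:8, each = 3), 1:3),
                    subject_id = rep(paste0("s", 1:8), each = 3),
                    role = "mouse", replicate = rep(1:3, 8))
  capacity <- setNames(seq(0, 0.28, length.out = 8), paste0("s", 1:8))
  metab <- simulate_phenotypes(capacity, man, cfg, seed = 5)
  expect_equal(nrow(metab), 24)
  expect_true(all(metab$tmao >= 0 & metab$choline >= 0))

  # a non-producer subject accumulates no TMAO and keeps maximal choline
  none <- metab[metab$sample_id %in% man$sample_id[man$subject_id == "s1"], ]
  expect_lt(max(none$tmao), 3 * cfg$tmao_noise_sd + 1e-9)
  expect_gt(mean(none$choline), cfg$choline_baseline - 3 * cfg$choline_noise_sd)

  fit <- linear_regression(metab$tmao, metab$choline)
  expect_lt(fit$slope, 0)

  # noiseless limit: choline is an exact linear function of TMAO
  cfg0 <- synthetic_config(tmao_noise_sd = 0, choline_noise_sd = 0)
  metab0 <- simulate_phenotypes(capacity, man, cfg0, seed = 5)
  fit0 <- suppressWarnings(linear_regression(metab0$tmao, metab0$choline))
  expect_equal(fit0$r_squared, 1)
})

test_that("generate_study assembles the full reproducible bundle", {
  st <- default_study()
  expect_equal(ncol(st$counts), 8 * (2 + 3))
  expect_equal(nrow(st$counts), 800)
  expect_equal(nrow(st$manifest), 40)
  expect_equal(sum(st$manifest$role == "mouse"), 24)
  expect_silent(validate_count_table(st$counts))
  expect_silent(validate_manifest(st$manifest, st$counts))
  expect_equal(sort(st$tree$tip.label), sort(rownames(st$counts)))

  st2 <- generate_study(synthetic_config(rng_seed = 1))
  expect_identical(st$counts, st2$counts)
  expect_identical(st$metabolites, st2$metabolites)
  expect_identical(ape::write.tree(st$tree), ape::write.tree(st2$tree))

  # integration smoke: the recovery stage has no undefined results
  rt <- recovery_table(st$counts, st$tax, st$manifest, "S2_vs_mouse")
  expect_false(any(rt$undefined))
  expect_equal(nrow(rt), 8 * 5)
})

test_that("study bundles round-trip through the file dialects", {
  st <- generate_study(synthetic_config(n_subjects = 2, n_otus = 40,
                                        reads_per_sample = 2000,
                                        rng_seed = 3))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(back$counts, st$counts)
  expect_equal(back$manifest, st$manifest)
  expect_equal(back$tax, st$tax)
  expect_equal(back$metabolites$tmao, st$metabolites$tmao, tolerance = 1e-9)
  expect_equal(sort(back$tree$tip.label), sort(st$tree$tip.label))
})

test_that("each mouse's nearest human community is its own donor", {
  st <- default_study()
  d <- as.matrix(distance_matrix(st$counts, "bray_curtis"))
  man <- st$manifest
  humans <- man[man$role %in% c("S1", "S2"), ]
  mice <- man[man$role == "mouse", ]
  hits <- vapply(seq_len(nrow(mice)), function(i) {
    dd <- d[mice$sample_id[i], humans$sample_id]
    humans$subject_id[which.min(dd)] == mice$subject_id[i]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
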