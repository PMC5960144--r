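test_that("inclusion rule is >= tau in at least one sample", {
  props <- cbind(R = toy_ref(), Q = toy_query())
  expect_equal(sum(inclusion_set(props, tau = 0.001)), 4)
  # f4 stays included at tau = 0.002 through its query abundance
  expect_equal(sum(inclusion_set(props, tau = 0.002)), 4)
  expect_equal(sum(inclusion_set(props, tau = 0.3)), 2)
  expect_equal(sum(inclusion_set(props * 1e-4, tau = 0.5)), 0)
  expect_error(inclusion_set(props[, 0]), "no samples")
})

test_that("taxa recovery counts detection within the inclusion set", {
  ref <- round(toy_ref() * 1000)
  qry <- round(toy_query() * 1000)
  rec <- taxa_recovery(ref, qry, tau = 0.001)
  expect_equal(rec$n_reference, 4)
  expect_equal(rec$n_recovered, 3)
  expect_equal(rec$recovery_pct, 75)
  expect_false(rec$undefined)

  self <- taxa_recovery(ref, ref, tau = 0.001)
  expect_equal(self$recovery_pct, 100)

  # empty reference: the inclusion set has no reference-detected taxon
  und <- taxa_recovery(c(0, 0), cbind(c(1000, 50)), tau = 0.01)
  expect_true(und$undefined)
  expect_true(is.na(und$recovery_pct))
})

test_that("abundance captured sums reference proportions of recovered taxa", {
  ref <- round(toy_ref() * 1000)
  qry <- round(toy_query() * 1000)
  expect_equal(abundance_captured(ref, qry), 80.1)
  expect_equal(abundance_captured(ref, ref), 100)
  expect_equal(abundance_captured(c(5, 5, 0), cbind(c(0, 0, 7))), 0)
  expect_error(abundance_captured(c(0, 0), cbind(c(1, 1))), "empty")
})

test_that("Venn partition splits the inclusion set consistently", {
  ref <- round(toy_ref() * 1000)
  qry <- round(toy_query() * 1000)
  expect_equal(venn_partition(ref, qry, tau = 0.001),
               c(reference_only = 1L, shared = 3L, query_only = 0L))
  expect_equal(venn_partition(ref, ref, tau = 0.001),
               c(reference_only = 0L, shared = 4L, query_only = 0L))
  expect_equal(venn_partition(c(9, 0), cbind(c(0, 4)), tau = 0.01),
               c(reference_only = 1L, shared = 0L, query_only = 1L))

  # shared count always equals n_recovered under any_mouse pooling
  set.seed(3)
  for (i in 1:25) {
    r <- rpois(30, 2)
    q <- matrix(rpois(90, 2), 30)
    if (sum(r) == 0 || any(colSums(q) == 0)) next
    rec <- taxa_recovery(r, q)
    vn <- venn_partition(r, q)
    expect_equal(unname(vn[["shared"]]), rec$n_recovered)
  }
})

test_that("recovery is invariant to feature order, scaling, and sub-threshold features", {
  set.seed(8)
  r <- rpois(40, 5) * rbinom(40, 1, 0.8)
  q <- matrix(rpois(120, 5) * rbinom(120, 1, 0.8), 40)
  base <- taxa_recovery(r, q)

  perm <- sample(40)
  expect_equal(taxa_recovery(r[perm], q[perm, ])$recovery_pct,
               base$recovery_pct)

  expect_equal(taxa_recovery(r * 13L, q)$recovery_pct, base$recovery_pct)
  expect_equal(taxa_recovery(r, q * 5L)$recovery_pct, base$recovery_pct)

  # adding a feature below tau everywhere changes no statistic
  r2 <- c(r, 0L)
  q2 <- rbind(q, 0L)
  expect_equal(taxa_recovery(r2, q2)$recovery_pct, base$recovery_pct)
  expect_equal(abundance_captured(r2, q2), abundance_captured(r, q))
})

test_that("per_mouse_mean pooling averages detection over query samples", {
  r <- c(100, 100, 100, 100)
  q <- cbind(c(100, 100, 0, 0), c(100, 100, 100, 0))
  any_pool <- taxa_recovery(r, q, pooling = "any_mouse")
  per_pool <- taxa_recovery(r, q, pooling = "per_mouse_mean")
  expect_equal(any_pool$recovery_pct, 75)
  expect_equal(per_pool$recovery_pct, 100 * mean(c(2, 3)) / 4)
  expect_equal(abundance_captured(r, q, pooling = "per_mouse_mean"),
               100 * mean(c(0.5, 0.75)))
})

test_that("summaries report mean and SD/sqrt(n) standard errors", {
  df <- data.frame(subject_id = c("a", "b", "c"), comparison = "S1_vs_S2",
                   rank = "OTU", n_included = 10, n_reference = 10,
                   n_recovered = c(7, 8, 9),
                   recovery_pct = c(70, 80, 90),
                   abundance_captured_pct = c(100, 100, 100),
                   venn_reference_only = 0, venn_shared = 0,
                   venn_query_only = 0, undefined = FALSE)
  s <- summarize_recovery(df)
  expect_equal(s$mean_recovery_pct, 80)
  expect_equal(s$se_recovery_pct, 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(s$se_abundance_captured_pct, 0)
  expect_equal(s$n_subjects, 3)

  s1 <- summarize_recovery(df[1, ])
  expect_true(is.na(s1$se_recovery_pct))

  # undefined rows are excluded
  df$undefined[3] <- TRUE
  expect_equal(summarize_recovery(df)$mean_recovery_pct, 75)
})

test_that("recovery_table gives exact self-recovery and respects the design", {
  st <- default_study()
  # self-comparison: duplicate S2 as its own query
  man <- st$manifest[st$manifest$subject_id %in% c("sub1", "sub2"), ]
  rt <- recovery_table(st$counts, st$tax, man, "S1_vs_S2")
  expect_true(all(rt$rank %in% tax_ranks()))
  expect_true(all(rt$recovery_pct >= 0 & rt$recovery_pct <= 100, na.rm = TRUE))
  expect_true(all(rt$n_recovered <= rt$n_reference))
  expect_true(all(rt$n_reference <= rt$n_included))

  # a subject lacking the reference sample is skipped silently
  man2 <- man[!(man$subject_id == "sub1" & man$role == "S1"), ]
  rt2 <- recovery_table(st$counts, st$tax, man2, "S1_vs_S2", ranks = "OTU")
  expect_equal(unique(rt2$subject_id), "sub2")
})

test_that("self-recovery is exactly 100% at every rank", {
  st <- default_study()
  sm <- st$manifest[st$manifest$subject_id == "sub3", ]
  s2 <- st$counts[, sm$sample_id[sm$role == "S2"]]
  for (r in c("phylum", "order", "family", "genus", "OTU")) {
    agg <- aggregate_by_rank(st$counts, st$tax, r)[, sm$sample_id[sm$role == "S2"]]
    rec <- taxa_recovery(agg, agg)
    expect_equal(rec$recovery_pct, 100, info = r)
    expect_equal(abundance_captured(agg, agg), 100, info = r)
  }
})

test_that("donor matching separates DONOR from OTHER distances", {
  # 2 subjects x (1 human, 1 mouse): counting
  man <- data.frame(sample_id = c("h1", "m1", "h2", "m2"),
                    subject_id = c("a", "a", "b", "b"),
                    role = c("S2", "mouse", "S2", "mouse"),
                    replicate = 1L)
  m <- matrix(0.5, 4, 4, dimnames = list(man$sample_id, man$sample_id))
  diag(m) <- 0
  m["h1", "m1"] <- m["m1", "h1"] <- 0
  m["h2", "m2"] <- m["m2", "h2"] <- 0.1
  dm <- donor_matching_distances(m, man)
  expect_equal(sum(dm$group == "DONOR"), 2)
  expect_equal(sum(dm$group == "OTHER"), 2)
  expect_lt(median(dm$distance[dm$group == "DONOR"]),
            median(dm$distance[dm$group == "OTHER"]))

  # subject with mice but no human sample -> skipped with warning
  man2 <- rbind(man, data.frame(sample_id = "m3", subject_id = "c",
                                role = "mouse", replicate = 1L))
  m2 <- rbind(cbind(m, m3 = 0.5), m3 = c(rep(0.5, 4), 0))
  expect_warning(dm2 <- donor_matching_distances(m2, man2), "c")
  expect_false("m3" %in% dm2$mouse_id)
})

test_that("donor matching on a simulated study rejects under Kruskal-Wallis", {
  res <- default_analysis()
  bc <- res$donor_other$bray_curtis
  expect_lt(bc$median_donor, bc$median_other)
  expect_lt(bc$kruskal_wallis$p_value, 0.05)
})
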