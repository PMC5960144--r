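# End-to-end orchestration: recovery statistics on un-rarefied counts,
# distance-based analyses on rarefied counts, permutation/rank tests, and the
# serum metabolite regression, with optional TSV output.

#' Run the full engraftment-fidelity analysis for one study
#'
#' Applies the study's analysis sequence: (a) per-subject recovery statistics
#' and summaries at all requested ranks for S1-vs-S2 and S2-vs-mouse, on
#' un-rarefied counts and under both query-pooling policies; (b) the four
#' beta-diversity distance matrices on counts rarefied to `depth`; (c)
#' PERMANOVA of S1-vs-S2 (stratified by subject) and of mouse samples by
#' donor, plus the DONOR/OTHER Kruskal-Wallis comparison per metric; (d) a
#' paired Wilcoxon signed-rank comparison of S1/S2 Shannon diversity on
#' rarefied counts (reported in place of the mixed-effects model, which is
#' out of scope); (e) the serum TMAO-vs-choline regression when metabolites
#' are supplied.
#'
#' @param counts Count table (features x samples), or a `synthetic_study`
#'   list from [generate_study()] (in which case the other data arguments are
#'   taken from it).
#' @param tax Taxonomy data frame.
#' @param tree Rooted tree (for the UniFrac metrics).
#' @param manifest Sample manifest.
#' @param metabolites Optional serum metabolite table.
#' @param tau Inclusion threshold (default 0.001).
#' @param ranks Ranks for the recovery stage.
#' @param depth Rarefaction depth for the distance stage (default 4500).
#' @param n_perm Permutations for PERMANOVA (default 999).
#' @param alpha Significance level echoed into the log (default 0.05).
#' @param seed Seed for rarefaction and permutation draws.
#' @param outdir Optional directory; when given, all result tables are
#'   written there as TSV together with a run log.
#' @return List with elements `recovery` (tables + summaries per comparison
#'   and pooling), `distances`, `permanova`, `donor_other`, `shannon`,
#'   `regression` (or `NULL`), and `log`.
#' @export
run_study_analysis <- function(counts, tax = NULL, tree = NULL,
                               manifest = NULL, metabolites = NULL,
                               tau = 0.001,
                               ranks = c("phylum", "order", "family",
                                         "genus", "OTU"),
                               depth = 4500, n_perm = 999, alpha = 0.05,
                               seed = 1, outdir = NULL) {
  if (inherits(counts, "synthetic_study")) {
    study <- counts
    counts <- study$counts
    tax <- study$tax
    tree <- study$tree
    manifest <- study$manifest
    if (is.null(metabolites)) metabolites <- study$metabolites
  }
  validate_count_table(counts)
  validate_manifest(manifest, counts)

  # --- recovery stage: un-rarefied counts ---
  recovery <- list()
  for (cmp in c("S1_vs_S2", "S2_vs_mouse")) {
    for (pool in c("any_mouse", "per_mouse_mean")) {
      tab <- recovery_table(counts, tax, manifest, comparison = cmp,
                            tau = tau, ranks = ranks, pooling = pool)
      recovery[[cmp]][[pool]] <- list(table = tab,
                                      summary = summarize_recovery(tab))
    }
  }

  # --- distance stage: rarefied counts ---
  rare <- rarefy(counts, depth = depth, seed = seed)
  metrics <- c("bray_curtis", "jaccard", "unweighted_unifrac",
               "weighted_unifrac")
  distances <- lapply(setNames(metrics, metrics), function(m)
    distance_matrix(rare, metric = m, tree = tree))

  rare_manifest <- manifest[manifest$sample_id %in% colnames(rare), ]
  human <- rare_manifest[rare_manifest$role %in% c("S1", "S2"), ]
  mice <- rare_manifest[rare_manifest$role == "mouse", ]

  d_uw <- as.matrix(distances$unweighted_unifrac)
  perm <- list()
  if (nrow(human) >= 4 && length(unique(human$role)) == 2) {
    hd <- d_uw[human$sample_id, human$sample_id]
    perm$s1_vs_s2 <- permanova(hd, human$role, n_perm = n_perm,
                               seed = seed + 1, strata = human$subject_id)
  }
  if (nrow(mice) >= 4 && length(unique(mice$subject_id)) >= 2) {
    md <- d_uw[mice$sample_id, mice$sample_id]
    perm$mouse_by_subject <- permanova(md, mice$subject_id, n_perm = n_perm,
                                       seed = seed + 2)
  }

  donor_other <- lapply(distances, function(d) {
    dm <- donor_matching_distances(d, rare_manifest)
    kw <- kruskal_wallis(split(dm$distance, dm$group))
    list(distances = dm,
         median_donor = median(dm$distance[dm$group == "DONOR"]),
         median_other = median(dm$distance[dm$group == "OTHER"]),
         kruskal_wallis = kw)
  })

  # --- alpha diversity on rarefied counts ---
  shannon_vals <- apply(rare, 2, shannon)
  coverage <- apply(rare, 2, goods_coverage)
  shannon_test <- NULL
  pairs <- merge(human[human$role == "S1", c("subject_id", "sample_id")],
                 human[human$role == "S2", c("subject_id", "sample_id")],
                 by = "subject_id", suffixes = c("_s1", "_s2"))
  if (nrow(pairs) >= 2) {
    wt <- suppressWarnings(wilcox.test(shannon_vals[pairs$sample_id_s1],
                                       shannon_vals[pairs$sample_id_s2],
                                       paired = TRUE))
    shannon_test <- list(method = "paired Wilcoxon signed-rank (S1 vs S2)",
                         statistic = unname(wt$statistic),
                         p_value = wt$p.value)
  }

  regression <- NULL
  if (!is.null(metabolites) && nrow(metabolites) >= 3) {
    regression <- linear_regression(metabolites$choline, metabolites$tmao)
  }

  log <- list(
    package_version = as.character(utils::packageVersion("engraftr")),
    seed = seed, tau = tau, depth = depth, n_perm = n_perm, alpha = alpha,
    ranks = ranks,
    n_samples = ncol(counts), n_features = nrow(counts),
    n_samples_rarefied = ncol(rare),
    note = paste("recovery computed on un-rarefied counts;",
                 "distances and alpha diversity on counts rarefied to",
                 depth))

  res <- list(recovery = recovery, distances = distances, permanova = perm,
              donor_other = donor_other,
              alpha_diversity = data.frame(sample_id = colnames(rare),
                                           shannon = as.numeric(shannon_vals),
                                           goods_coverage = as.numeric(coverage),
                                           stringsAsFactors = FALSE),
              shannon = shannon_test, regression = regression, log = log)
  if (!is.null(outdir)) write_analysis(res, outdir)
  res
}

# Serialize a run_study_analysis() result as long-format TSVs plus a log.
write_analysis <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (cmp in names(res$recovery)) {
    for (pool in names(res$recovery[[cmp]])) {
      base <- sprintf("recovery_%s_%s", tolower(cmp), pool)
      write.table(res$recovery[[cmp]][[pool]]$table,
                  file.path(outdir, paste0(base, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$recovery[[cmp]][[pool]]$summary,
                  file.path(outdir, paste0(base, "_summary.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (m in names(res$distances))
    write_distance_matrix(res$distances[[m]],
                          file.path(outdir, paste0("distance_", m, ".tsv")))
  stats <- list()
  for (nm in names(res$permanova)) {
    p <- res$permanova[[nm]]
    stats[[length(stats) + 1]] <- data.frame(
      analysis = paste0("permanova_", nm), statistic = "pseudo_F",
      value = p$pseudo_F, p_value = p$p_value)
  }
  for (m in names(res$donor_other)) {
    d <- res$donor_other[[m]]
    stats[[length(stats) + 1]] <- data.frame(
      analysis = paste0("donor_vs_other_", m), statistic = "kruskal_wallis_H",
      value = d$kruskal_wallis$H, p_value = d$kruskal_wallis$p_value)
  }
  if (!is.null(res$shannon))
    stats[[length(stats) + 1]] <- data.frame(
      analysis = "shannon_s1_vs_s2", statistic = "wilcoxon_V",
      value = res$shannon$statistic, p_value = res$shannon$p_value)
  if (!is.null(res$regression))
    stats[[length(stats) + 1]] <- data.frame(
      analysis = "tmao_vs_choline", statistic = "r_squared",
      value = res$regression$r_squared, p_value = res$regression$p_value)
  if (length(stats))
    write.table(do.call(rbind, stats), file.path(outdir, "stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$alpha_diversity, file.path(outdir, "alpha_diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(names(res$log),
                   vapply(res$log, function(x) paste(x, collapse = " "), ""),
                   sep = ": "),
             file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
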