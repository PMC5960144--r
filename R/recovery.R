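# The study's core statistic set: inclusion-thresholded taxa recovery between
# paired samples (straw aliquots, or gavage inoculum vs recipient mice),
# percent relative abundance captured, Venn partitions of the inclusion set,
# and per-subject summaries. All recovery statistics are computed on
# un-rarefied counts; the inclusion rule works on per-sample proportions.

#' Inclusion set under the relative-abundance threshold
#'
#' A feature enters a comparison if its relative abundance is at least `tau`
#' in at least one of the provided samples. For inoculum-vs-mouse comparisons
#' the group is the reference plus all of the subject's mouse samples.
#'
#' @param props Proportion matrix (features x samples) or a list of
#'   proportion vectors sharing a feature universe.
#' @param tau Inclusion threshold as a proportion (study default 0.001,
#'   i.e. 0.1%); the rule is inclusive (`>= tau`).
#' @return Logical vector over features.
#' @export
inclusion_set <- function(props, tau = 0.001) {
  if (is.list(props) && !is.data.frame(props)) props <- do.call(cbind, props)
  props <- as.matrix(props)
  if (ncol(props) == 0) stop("no samples provided")
  stopifnot(tau > 0, tau < 1)
  rowSums(props >= tau) > 0
}

# detection of each feature in the query group: logical matrix features x
# queries -> per-feature detection under the pooling policy (any_mouse) or
# per-query columns (per_mouse_mean handled by callers averaging per query).
.detected_any <- function(query) rowSums(query > 0) > 0

#' Taxa recovery between a reference sample and a query group
#'
#' The number of inclusion-set taxa detected in the reference
#' (`n_reference`), the number of those also detected (raw count > 0) in the
#' query group (`n_recovered`), and their ratio as a percentage. With
#' `pooling = "any_mouse"` a taxon counts as recovered if present in at least
#' one query sample; with `"per_mouse_mean"` the percentage is computed per
#' query sample and averaged.
#'
#' @param reference Count vector for the reference sample (e.g. S1 or S2).
#' @param query Count vector or matrix (features x query samples), e.g. S2 or
#'   the subject's mouse samples.
#' @param tau Inclusion threshold (proportion).
#' @param pooling `"any_mouse"` or `"per_mouse_mean"`.
#' @return List with `n_included`, `n_reference`, `n_recovered`,
#'   `recovery_pct` and `undefined` (TRUE when no reference taxon passes the
#'   inclusion rule, in which case the percentage is `NA`).
#' @export
taxa_recovery <- function(reference, query, tau = 0.001,
                          pooling = c("any_mouse", "per_mouse_mean")) {
  pooling <- match.arg(pooling)
  query <- as.matrix(query)
  props <- cbind(reference / max(sum(reference), 1e-300),
                 sweep(query, 2, pmax(colSums(query), 1e-300), "/"))
  incl <- inclusion_set(props, tau)
  in_ref <- incl & reference > 0
  n_reference <- sum(in_ref)
  if (n_reference == 0) {
    return(list(n_included = sum(incl), n_reference = 0L, n_recovered = 0L,
                recovery_pct = NA_real_, undefined = TRUE))
  }
  if (pooling == "any_mouse") {
    n_recovered <- sum(in_ref & .detected_any(query))
    pct <- 100 * n_recovered / n_reference
  } else {
    per <- apply(query > 0, 2, function(d) sum(in_ref & d))
    n_recovered <- as.integer(round(mean(per)))
    pct <- 100 * mean(per) / n_reference
  }
  list(n_included = sum(incl), n_reference = n_reference,
       n_recovered = as.integer(n_recovered), recovery_pct = pct,
       undefined = FALSE)
}

#' Percent relative abundance of the reference captured by the query group
#'
#' Sums the reference-sample relative abundance of every reference feature
#' that is detected in the query group. No inclusion threshold is applied:
#' all features present in the reference contribute to the denominator.
#'
#' @inheritParams taxa_recovery
#' @return Percentage in \[0, 100\].
#' @export
abundance_captured <- function(reference, query,
                               pooling = c("any_mouse", "per_mouse_mean")) {
  pooling <- match.arg(pooling)
  if (sum(reference) <= 0) stop("reference sample is empty")
  query <- as.matrix(query)
  refp <- reference / sum(reference)
  if (pooling == "any_mouse") {
    100 * sum(refp[reference > 0 & .detected_any(query)])
  } else {
    100 * mean(apply(query > 0, 2, function(d) sum(refp[reference > 0 & d])))
  }
}

#' Venn partition of the inclusion set
#'
#' Splits the inclusion-set features into those detected only in the
#' reference, in both, or only in the query group.
#'
#' @inheritParams taxa_recovery
#' @return Named integer vector `(reference_only, shared, query_only)`.
#' @export
venn_partition <- function(reference, query, tau = 0.001,
                           pooling = c("any_mouse", "per_mouse_mean")) {
  pooling <- match.arg(pooling)
  query <- as.matrix(query)
  props <- cbind(reference / max(sum(reference), 1e-300),
                 sweep(query, 2, pmax(colSums(query), 1e-300), "/"))
  incl <- inclusion_set(props, tau)
  det <- .detected_any(query)
  c(reference_only = sum(incl & reference > 0 & !det),
    shared = sum(incl & reference > 0 & det),
    query_only = sum(incl & reference == 0 & det))
}

#' Per-subject recovery statistics across taxonomic ranks
#'
#' Runs the full recovery statistic set over every subject of a study, for
#' either the aliquot comparison (S1 as reference, S2 as query) or the
#' engraftment comparison (S2 as reference, the subject's mouse samples as
#' query group). Uses un-rarefied counts throughout.
#'
#' @param counts Count table (features x samples).
#' @param tax Taxonomy data frame (needed for ranks above OTU).
#' @param manifest Sample manifest.
#' @param comparison `"S1_vs_S2"` or `"S2_vs_mouse"`.
#' @param tau Inclusion threshold (proportion).
#' @param ranks Ranks to evaluate (default phylum, order, family, genus, OTU).
#' @param pooling Query-group pooling policy, see [taxa_recovery()].
#' @return Data frame with one row per subject x rank: inclusion counts,
#'   recovery percentage, abundance captured, and the Venn partition.
#' @export
recovery_table <- function(counts, tax = NULL, manifest,
                           comparison = c("S1_vs_S2", "S2_vs_mouse"),
                           tau = 0.001,
                           ranks = c("phylum", "order", "family", "genus", "OTU"),
                           pooling = c("any_mouse", "per_mouse_mean")) {
  comparison <- match.arg(comparison)
  pooling <- match.arg(pooling)
  validate_manifest(manifest, counts)
  ranks <- vapply(ranks, match.arg, "", choices = tax_ranks())
  if (any(ranks != "OTU") && is.null(tax))
    stop("taxonomy required for ranks above OTU")
  ref_role <- if (comparison == "S1_vs_S2") "S1" else "S2"
  agg <- lapply(setNames(ranks, ranks), function(r)
    aggregate_by_rank(counts, tax, r))
  out <- list()
  for (subject in unique(manifest$subject_id)) {
    sm <- manifest[manifest$subject_id == subject, ]
    ref_id <- sm$sample_id[sm$role == ref_role]
    query_ids <- if (comparison == "S1_vs_S2") {
      sm$sample_id[sm$role == "S2"]
    } else {
      sm$sample_id[sm$role == "mouse"]
    }
    if (length(ref_id) != 1 || length(query_ids) == 0) next
    for (r in ranks) {
      m <- agg[[r]]
      ref <- m[, ref_id]
      qry <- m[, query_ids, drop = FALSE]
      rec <- taxa_recovery(ref, qry, tau, pooling)
      ab <- abundance_captured(ref, qry, pooling)
      vn <- venn_partition(ref, qry, tau)
      out[[length(out) + 1]] <- data.frame(
        subject_id = subject, comparison = comparison, rank = r,
        n_included = rec$n_included, n_reference = rec$n_reference,
        n_recovered = rec$n_recovered, recovery_pct = rec$recovery_pct,
        abundance_captured_pct = ab,
        venn_reference_only = vn[["reference_only"]],
        venn_shared = vn[["shared"]], venn_query_only = vn[["query_only"]],
        undefined = rec$undefined, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no subject had the samples required for ", comparison)
  do.call(rbind, out)
}

#' Summarize recovery across subjects
#'
#' Mean and standard error (sample SD / sqrt(n)) per rank over subjects,
#' excluding undefined results. Single-subject ranks get `NA` SE.
#'
#' @param results Data frame from [recovery_table()].
#' @return Data frame with one row per rank: `n_subjects`, `mean_recovery_pct`,
#'   `se_recovery_pct`, `mean_abundance_captured_pct`,
#'   `se_abundance_captured_pct`.
#' @export
summarize_recovery <- function(results) {
  results <- results[!results$undefined, , drop = FALSE]
  se <- function(v) if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  out <- lapply(split(results, factor(results$rank, unique(results$rank))),
                function(df) data.frame(
    rank = df$rank[1],
    n_subjects = nrow(df),
    mean_recovery_pct = mean(df$recovery_pct),
    se_recovery_pct = se(df$recovery_pct),
    mean_abundance_captured_pct = mean(df$abundance_captured_pct),
    se_abundance_captured_pct = se(df$abundance_captured_pct),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Donor-matched vs non-donor distances
#'
#' For every mouse sample, collects its distances to its own subject's human
#' samples (`DONOR`) and to every other subject's human samples (`OTHER`).
#' Both straw aliquots (S1 and S2) count as human samples when present.
#'
#' @param d Distance matrix ([stats::dist] or square matrix) over samples that
#'   include both mouse and human samples.
#' @param manifest Sample manifest covering those samples.
#' @return Data frame with columns `mouse_id`, `human_id`, `subject_id` (the
#'   mouse's subject), `group` (`DONOR`/`OTHER`), `distance`.
#' @export
donor_matching_distances <- function(d, manifest) {
  m <- as.matrix(d)
  manifest <- manifest[manifest$sample_id %in% rownames(m), , drop = FALSE]
  mice <- manifest[manifest$role == "mouse", , drop = FALSE]
  humans <- manifest[manifest$role %in% c("S1", "S2"), , drop = FALSE]
  if (nrow(mice) == 0 || nrow(humans) == 0)
    stop("distance matrix must cover both mouse and human samples")
  orphan <- setdiff(mice$subject_id, humans$subject_id)
  if (length(orphan)) {
    warning("mice skipped for subject(s) without a human sample: ",
            paste(orphan, collapse = ", "))
    mice <- mice[!mice$subject_id %in% orphan, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(mice))) {
    grp <- ifelse(humans$subject_id == mice$subject_id[i], "DONOR", "OTHER")
    out[[i]] <- data.frame(
      mouse_id = mice$sample_id[i], human_id = humans$sample_id,
      subject_id = mice$subject_id[i], group = grp,
      distance = m[mice$sample_id[i], humans$sample_id],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
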