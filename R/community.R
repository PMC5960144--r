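# Core transformations on count tables: relative abundance, taxonomic
# aggregation, rarefaction, Shannon diversity, Good's coverage.

#' Convert counts to per-sample relative abundances
#'
#' @param x Count table (features x samples).
#' @return Matrix of proportions; every non-empty sample column sums to 1.
#'   All-zero samples stay zero, with a warning.
#' @export
relative_abundance <- function(x) {
  validate_count_table(x)
  tot <- colSums(x)
  if (any(tot == 0))
    warning("all-zero sample(s): ", paste(colnames(x)[tot == 0], collapse = ", "))
  sweep(x, 2, pmax(tot, 1), "/")
}

#' Aggregate a count table to a taxonomic rank
#'
#' Features sharing the same label at `rank` are summed. `rank = "OTU"`
#' returns the table unchanged (feature IDs are the OTU level).
#'
#' @param x Count table (features x samples).
#' @param tax Taxonomy data frame from [read_taxonomy()].
#' @param rank One of [tax_ranks()].
#' @return Count table whose feature IDs are the labels at `rank`.
#' @export
aggregate_by_rank <- function(x, tax, rank) {
  rank <- match.arg(rank, tax_ranks())
  if (rank == "OTU") return(x)
  idx <- match(rownames(x), tax$feature_id)
  if (anyNA(idx))
    stop("feature(s) missing from taxonomy: ",
         paste(rownames(x)[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
  labels <- tax[[rank]][idx]
  out <- rowsum(x, group = labels)
  storage.mode(out) <- storage.mode(x)
  out
}

#' Rarefy a count table to fixed depth
#'
#' Each sample with at least `depth` reads is subsampled to exactly `depth`
#' reads without replacement (multivariate hypergeometric, via
#' [vegan::rrarefy()]); shallower samples are dropped with a warning.
#'
#' @param x Count table (features x samples).
#' @param depth Target reads per sample (study default 4500).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Rarefied count table; every column sums to `depth`.
#' @export
rarefy <- function(x, depth = 4500, seed = 1) {
  validate_count_table(x)
  stopifnot(depth >= 1)
  keep <- colSums(x) >= depth
  if (!any(keep)) stop("all samples are below rarefaction depth ", depth)
  if (!all(keep))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(x)[!keep], collapse = ", "))
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(x[, keep, drop = FALSE]), depth)),
    warning = function(w) {
      # vegan heuristically warns whenever the smallest count is large;
      # irrelevant for genuine integer count tables
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Good's coverage of a sample
#'
#' `1 - singletons / reads`: the estimated probability that the next read
#' belongs to an already-observed feature.
#'
#' @param counts Integer count vector for one sample.
#' @return Coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("sample has zero total count")
  1 - sum(counts == 1) / total
}

#' Shannon diversity of a sample (natural log)
#'
#' @param counts Integer count vector for one sample.
#' @return Shannon index H in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("sample has zero total count")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}
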