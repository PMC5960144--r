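# Readers and writers for the plain-text artifacts the pipeline exchanges:
# count tables, taxonomy, newick trees, sample manifests, distance matrices
# and serum metabolite tables. All tabular formats are TSV.

#' Validate a feature-by-sample count table
#'
#' A count table is a non-negative integer matrix with features in rows and
#' samples in columns, both uniquely named.
#'
#' @param x Matrix to validate.
#' @return `x`, invisibly, after validation.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("count table needs at least 1 feature and 1 sample")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have feature and sample names")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) stop("duplicated feature ID(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup)) stop("duplicated sample ID(s): ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid count at feature '%s', sample '%s' (must be a non-negative integer)",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  invisible(x)
}

#' Read a count table from TSV
#'
#' Expects a header row of sample IDs; the first column holds feature IDs and
#' the remaining columns integer counts.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file is samples-in-rows and is transposed
#'   on read to the package's features-in-rows orientation.
#' @return Integer matrix, features in rows, samples in columns.
#' @export
read_count_table <- function(path, transpose = FALSE) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated column ID(s) in header: ", paste(dup, collapse = ", "))
  df <- read.delim(path, check.names = FALSE, colClasses = c("character"),
                   stringsAsFactors = FALSE)
  dup <- unique(df[[1]][duplicated(df[[1]])])
  if (length(dup)) stop("duplicated row ID(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  rownames(m) <- df[[1]]
  colnames(m) <- ids
  if (transpose) m <- t(m)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at row '%s', column '%s' in %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  }
  storage.mode(m) <- "integer"
  validate_count_table(m)
  m
}

#' Write a count table to TSV
#'
#' @param x Count table (features x samples).
#' @param path Output path.
#' @param id_column Name for the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, id_column = "feature_id") {
  validate_count_table(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split one GreenGenes-style lineage string into the six ranks, stripping
# "k__"-style prefixes and "(97)"-style confidences, and filling unnamed deep
# ranks with unclassified_<deepest named ancestor>.
parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- sub("\\(\\d+\\)$", "", parts)          # strip trailing confidences
  parts <- sub("^[a-zA-Z]__", "", parts)          # strip rank prefixes
  parts <- trimws(parts)
  if (length(parts) > length(TAX_RANKS))
    stop("malformed lineage (more than ", length(TAX_RANKS), " ranks): ", lineage)
  out <- character(length(TAX_RANKS))
  out[seq_along(parts)] <- parts
  if (!nzchar(out[1]))
    stop("malformed lineage (no kingdom label): ", lineage)
  for (i in seq_along(out)[-1]) {
    if (!nzchar(out[i])) {
      anc <- out[i - 1]
      out[i] <- if (startsWith(anc, "unclassified_")) anc
                else paste0("unclassified_", anc)
    }
  }
  names(out) <- TAX_RANKS
  out
}

#' Read a taxonomy table from TSV
#'
#' Two columns: feature ID and a GreenGenes-dialect lineage string
#' (`"k__Bacteria;p__Firmicutes;..."`). Rank prefixes and per-rank confidence
#' annotations are stripped; unnamed deep ranks become
#' `unclassified_<deepest named ancestor>`.
#'
#' @param path Path to a TSV file (no header, or header starting `feature`).
#' @return Data frame with columns `feature_id`, `kingdom`, ..., `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) && grepl("^feature", df[1, 1], ignore.case = TRUE))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop("taxonomy file needs feature_id and lineage columns")
  dup <- unique(df[[1]][duplicated(df[[1]])])
  if (length(dup)) stop("duplicated feature ID(s): ", paste(dup, collapse = ", "))
  ranks <- t(vapply(df[[2]], parse_lineage, character(length(TAX_RANKS))))
  out <- data.frame(feature_id = df[[1]], ranks, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Write a taxonomy table to TSV
#'
#' Inverse of [read_taxonomy()]: lineages are serialized back into the
#' prefixed `k__...;p__...` dialect.
#'
#' @param tax Taxonomy data frame (`feature_id` plus the six rank columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  lineage <- apply(tax[, TAX_RANKS, drop = FALSE], 1, function(r)
    paste0(prefixes, r, collapse = ";"))
  write.table(data.frame(tax$feature_id, lineage), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Wraps [ape::read.tree()] with validation: duplicate leaf labels are an
#' error, missing branch lengths become 0 with a warning, negative or
#' non-finite lengths are an error.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick in ", path)
  validate_tree(tree)
}

#' Validate a phylogenetic tree for use in UniFrac
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, with any missing branch lengths replaced by 0 (warning).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicated leaf label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length) | tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

MANIFEST_ROLES <- c("S1", "S2", "mouse")

#' Validate a sample manifest
#'
#' A manifest maps each sample to `(subject_id, role, replicate)` with roles
#' drawn from `S1` (extraction aliquot), `S2` (gavage aliquot) and `mouse`
#' (recipient fecal sample). Each subject may have at most one S1 and one S2.
#'
#' @param manifest Data frame with columns `sample_id`, `subject_id`, `role`,
#'   `replicate`.
#' @param counts Optional count table; if given, every manifest sample must be
#'   one of its columns.
#' @return The manifest, invisibly.
#' @export
validate_manifest <- function(manifest, counts = NULL) {
  need <- c("sample_id", "subject_id", "role", "replicate")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(manifest$role), MANIFEST_ROLES)
  if (length(bad))
    stop("unknown role(s) ", paste(bad, collapse = ", "),
         "; valid roles are: ", paste(MANIFEST_ROLES, collapse = ", "))
  dup <- unique(manifest$sample_id[duplicated(manifest$sample_id)])
  if (length(dup)) stop("duplicated sample ID(s): ", paste(dup, collapse = ", "))
  rep_ <- manifest$replicate
  if (any(!is.finite(rep_) | rep_ < 1 | rep_ != round(rep_)))
    stop("replicate must be a positive integer")
  for (role in c("S1", "S2")) {
    tab <- table(manifest$subject_id[manifest$role == role])
    if (any(tab > 1))
      stop("subject(s) with more than one ", role, " sample: ",
           paste(names(tab)[tab > 1], collapse = ", "))
  }
  if (!is.null(counts)) {
    miss <- setdiff(manifest$sample_id, colnames(counts))
    if (length(miss))
      stop("manifest sample(s) absent from count table: ",
           paste(miss, collapse = ", "))
  }
  invisible(manifest)
}

#' Read a sample manifest from TSV
#'
#' @param path Path to a TSV with columns `sample_id`, `subject_id`, `role`,
#'   `replicate`.
#' @param counts Optional count table for cross-validation.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path, counts = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_manifest(df, counts)
  df
}

#' Write a sample manifest to TSV
#'
#' @param manifest Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a serum metabolite table from TSV
#'
#' @param path Path to a TSV with columns `sample_id`, `tmao`, `choline`
#'   (concentrations, arbitrary units).
#' @return Data frame with finite non-negative metabolite values.
#' @export
read_metabolites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tmao", "choline")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metabolite table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("tmao", "choline")) {
    if (any(!is.finite(df[[col]]) | df[[col]] < 0))
      stop("non-finite or negative values in column '", col, "'")
  }
  df
}

#' Write a serum metabolite table to TSV
#'
#' @param metab Metabolite data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolites <- function(metab, path) {
  write.table(metab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as square labeled TSV
#'
#' @param d A [stats::dist] object or square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labeled distance matrix from TSV
#'
#' @param path Path written by [write_distance_matrix()].
#' @return A [stats::dist] object.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!isTRUE(all.equal(rownames(m), colnames(m))))
    stop("distance matrix row and column labels differ")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  stats::as.dist(m)
}
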