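#' @keywords internal
TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Sentinel label for unclassified taxonomy ranks
#'
#' OTUs that could not be classified at a rank carry this explicit label
#' rather than an empty or missing value, so aggregation pools them into a
#' visible bin instead of silently dropping them.
#' @export
UNCLASSIFIED <- "unclassified"

#' Construct an OTU count table
#'
#' The central container of the microbial side of the analysis: an integer
#' count matrix (samples in rows, OTUs in columns), a taxonomy path per OTU
#' from kingdom down to genus, and a two-level group factor over the samples.
#'
#' @param counts integer matrix, samples x OTUs, with unique dimnames.
#' @param taxonomy data.frame with one row per OTU (rownames matching
#'   `colnames(counts)`) and character columns `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`. Unclassified ranks must carry the
#'   [UNCLASSIFIED] sentinel, not `NA`.
#' @param groups factor (or character) of length `nrow(counts)`, named by
#'   sample id, assigning each sample to one of two groups (e.g. `"MC"` /
#'   `"LC"`).
#' @return An object of class `"otu_table"`: a list with elements `counts`,
#'   `taxonomy`, `groups`.
#' @export
otu_table <- function(counts, taxonomy, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"

  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  missing_ranks <- setdiff(TAXONOMY_RANKS, colnames(taxonomy))
  if (length(missing_ranks))
    stop("taxonomy lacks rank column(s): ", paste(missing_ranks, collapse = ", "))
  taxonomy <- taxonomy[, TAXONOMY_RANKS, drop = FALSE]
  if (!setequal(rownames(taxonomy), colnames(counts)))
    stop("taxonomy rownames must match OTU ids of the count matrix")
  taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  if (any(is.na(taxonomy)))
    stop("taxonomy may not contain NA; use the UNCLASSIFIED sentinel")

  if (is.null(names(groups))) {
    if (length(groups) != nrow(counts))
      stop("groups must be named by sample or match nrow(counts)")
    names(groups) <- rownames(counts)
  }
  if (!setequal(names(groups), rownames(counts)))
    stop("group names must match sample ids")
  groups <- factor(as.character(groups[rownames(counts)]))
  names(groups) <- rownames(counts)

  structure(list(counts = counts, taxonomy = taxonomy, groups = groups),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups: ", paste(sprintf("%s(n=%d)", levels(x$groups),
                                tabulate(x$groups)), collapse = ", "), "\n")
  cat(sprintf("taxa: %d phyla, %d genera (incl. sentinel)\n",
              length(unique(x$taxonomy$phylum)),
              length(unique(x$taxonomy$genus))))
  invisible(x)
}

n_samples <- function(x) nrow(x$counts)
n_otus <- function(x) ncol(x$counts)

check_two_groups <- function(groups, min_per_group = 2) {
  tab <- table(groups)
  if (length(tab) != 2)
    stop("group factor must have exactly 2 levels, got ", length(tab))
  if (any(tab < min_per_group))
    stop("each group needs at least ", min_per_group, " samples")
  invisible(TRUE)
}

## ---- taxonomy string handling (QIIME classic style) ----

taxonomy_to_string <- function(taxonomy) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  apply(taxonomy[, TAXONOMY_RANKS, drop = FALSE], 1L, function(row)
    paste0(prefixes, row, collapse = ";"))
}

string_to_taxonomy <- function(strings, otu_ids) {
  parts <- strsplit(strings, ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- sub("^\\s*[kpcofg]__", "", p)
    out <- rep(UNCLASSIFIED, 6L)
    out[seq_along(p)] <- ifelse(nzchar(p), p, UNCLASSIFIED)
    out[1:6]
  }, character(6)))
  colnames(mat) <- TAXONOMY_RANKS
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  rownames(df) <- otu_ids
  df
}

## ---- TSV interfaces ----

#' Write an OTU table as tab-separated text
#'
#' Rows are OTUs, columns are samples, first column `OTU_ID`, last column
#' `taxonomy` in the `k__...;p__...;...;g__...` convention.
#' @param x an [otu_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(OTU_ID = colnames(x$counts),
                   t(x$counts),
                   taxonomy = taxonomy_to_string(x$taxonomy),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table written by [write_otu_table()]
#'
#' @param path OTU TSV (rows OTUs, columns samples, plus `taxonomy`).
#' @param metadata_path sample metadata TSV with columns `sample_id`, `group`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, metadata_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", header = TRUE)
  meta <- read_sample_metadata(metadata_path)
  sample_cols <- setdiff(colnames(df), c("OTU_ID", "taxonomy"))
  if (nrow(df) == 0L) {
    counts <- matrix(0, nrow = length(sample_cols), ncol = 0,
                     dimnames = list(sample_cols, NULL))
    tax <- data.frame(matrix(character(0), 0, 6,
                             dimnames = list(NULL, TAXONOMY_RANKS)))
    return(structure(list(counts = counts, taxonomy = tax,
                          groups = meta[sample_cols]),
                     class = "otu_table"))
  }
  counts <- t(vapply(seq_len(nrow(df)),
                     function(i) as.numeric(df[i, sample_cols]),
                     numeric(length(sample_cols))))
  dimnames(counts) <- list(df$OTU_ID, sample_cols)
  taxonomy <- string_to_taxonomy(df$taxonomy, df$OTU_ID)
  otu_table(t(counts), taxonomy, meta[sample_cols])
}

#' Write sample metadata (`sample_id`, `group`) as TSV
#' @param groups named factor/character, names are sample ids.
#' @param path output file.
#' @export
write_sample_metadata <- function(groups, path) {
  utils::write.table(data.frame(sample_id = names(groups),
                                group = as.character(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata written by [write_sample_metadata()]
#' @param path metadata TSV.
#' @return named factor of groups.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("metadata needs columns sample_id, group")
  stats::setNames(factor(df$group), df$sample_id)
}
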