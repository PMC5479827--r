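#' Drop OTUs never seen above a minimal count
#'
#' Retains an OTU only if its count is strictly greater than `min_count` in
#' at least one sample, the usual guard against spurious singleton-level
#' OTUs. OTU order is preserved; an empty result is allowed.
#'
#' @param x an [otu_table].
#' @param min_count strict lower bound (default 3: an OTU must exceed 3
#'   reads somewhere to survive).
#' @return The filtered [otu_table].
#' @export
filter_min_count <- function(x, min_count = 3) {
  stopifnot(inherits(x, "otu_table"))
  keep <- if (ncol(x$counts)) apply(x$counts, 2L, max) > min_count else
    logical(0)
  structure(list(counts = x$counts[, keep, drop = FALSE],
                 taxonomy = x$taxonomy[keep, , drop = FALSE],
                 groups = x$groups),
            class = "otu_table")
}

#' Per-sample relative abundance profile
#'
#' Normalizes each sample's counts to fractions summing to one.
#'
#' @param x an [otu_table] (possibly rank-aggregated).
#' @return An object of class `"taxon_profile"`: list with `abund`
#'   (samples x taxa fractions), `rank`, `taxonomy`, `groups`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- rowSums(x$counts)
  bad <- names(tot)[tot == 0]
  if (length(bad))
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  structure(list(abund = x$counts / tot,
                 rank = attr(x, "rank") %||% "otu",
                 taxonomy = x$taxonomy,
                 groups = x$groups),
            class = "taxon_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("taxon_profile (%s): %d samples x %d taxa\n",
              x$rank, nrow(x$abund), ncol(x$abund)))
  invisible(x)
}

#' Sum counts hierarchically at a taxonomic rank
#'
#' OTUs sharing a label at `rank` are pooled; per-sample totals are conserved
#' exactly. OTUs unclassified at the rank are pooled under the
#' [UNCLASSIFIED] sentinel, never dropped.
#'
#' @param x an [otu_table].
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return An [otu_table] whose "OTUs" are the rank labels; taxonomy keeps
#'   the ranks down to `rank`. An attribute `"rank"` records the level.
#' @export
aggregate_at_rank <- function(x, rank) {
  stopifnot(inherits(x, "otu_table"))
  if (!rank %in% TAXONOMY_RANKS)
    stop("unknown rank: ", rank, " (expected one of ",
         paste(TAXONOMY_RANKS, collapse = ", "), ")")
  labels <- x$taxonomy[[rank]]
  agg <- t(rowsum(t(x$counts), group = labels, reorder = FALSE))
  upto <- seq_len(match(rank, TAXONOMY_RANKS))
  first <- !duplicated(labels)
  tax <- x$taxonomy[first, TAXONOMY_RANKS[upto], drop = FALSE]
  # an UNCLASSIFIED bin can straddle parents; blank its higher ranks too
  if (rank != "kingdom" && UNCLASSIFIED %in% labels) {
    amb <- labels == UNCLASSIFIED
    parents <- unique(x$taxonomy[amb, TAXONOMY_RANKS[upto[-length(upto)]],
                                 drop = FALSE])
    if (nrow(parents) > 1L)
      tax[match(UNCLASSIFIED, labels[first]),
          seq_len(length(upto) - 1L)] <- UNCLASSIFIED
  }
  rownames(tax) <- labels[first]
  missing_ranks <- setdiff(TAXONOMY_RANKS, colnames(tax))
  for (r in missing_ranks) tax[[r]] <- UNCLASSIFIED
  out <- otu_table(agg, tax[, TAXONOMY_RANKS], x$groups)
  attr(out, "rank") <- rank
  out
}

#' Keep taxa reaching a detectability threshold
#'
#' A taxon is "detectable" if its relative abundance reaches `threshold`
#' (inclusive, default 1%) in at least one sample.
#'
#' @param profile a [to_relative()] profile.
#' @param threshold inclusive fraction bound (default 0.01).
#' @return The filtered `"taxon_profile"` (fractions NOT renormalized; the
#'   removed remainder is implicit).
#' @export
detectable_filter <- function(profile, threshold = 0.01) {
  stopifnot(inherits(profile, "taxon_profile"))
  keep <- if (ncol(profile$abund)) apply(profile$abund, 2L, max) >= threshold
  else logical(0)
  profile$abund <- profile$abund[, keep, drop = FALSE]
  if (!is.null(profile$taxonomy))
    profile$taxonomy <- profile$taxonomy[keep, , drop = FALSE]
  profile
}

#' Percent change of a taxon's mean relative abundance between groups
#'
#' `100 * (mean(numerator group) - mean(denominator group)) / mean(denominator
#' group)`; e.g. +230 means the taxon's mean abundance more than tripled.
#'
#' @param profile a `"taxon_profile"`.
#' @param taxon taxon (column) name.
#' @param numerator,denominator group labels; defaults are the first and
#'   second factor level.
#' @return percent change (signed).
#' @export
group_percent_change <- function(profile, taxon, numerator = NULL,
                                 denominator = NULL) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (!taxon %in% colnames(profile$abund)) stop("unknown taxon: ", taxon)
  g <- profile$groups
  numerator <- numerator %||% levels(g)[1]
  denominator <- denominator %||% levels(g)[2]
  m_num <- mean(profile$abund[g == numerator, taxon])
  m_den <- mean(profile$abund[g == denominator, taxon])
  if (m_den == 0)
    stop("emergent taxon: ", taxon, " absent from group ", denominator,
         "; percent change undefined", call. = FALSE)
  100 * (m_num - m_den) / m_den
}

#' Partition taxa into shared and group-exclusive sets
#'
#' A taxon is "present" in a group when its count (or fraction) is positive
#' in at least one sample of that group. The three returned sets are
#' disjoint and jointly cover every observed taxon at the rank.
#'
#' @param x an [otu_table] or `"taxon_profile"`.
#' @param rank optional rank at which to aggregate first (tables only).
#' @return list with elements `shared`, plus one `<group>_only` set per
#'   group level.
#' @export
shared_taxa <- function(x, rank = NULL) {
  if (inherits(x, "otu_table")) {
    if (!is.null(rank)) x <- aggregate_at_rank(x, rank)
    mat <- x$counts
  } else if (inherits(x, "taxon_profile")) {
    mat <- x$abund
  } else stop("expected an otu_table or taxon_profile")
  g <- x$groups
  lv <- levels(g)
  observed <- colnames(mat)[colSums(mat) > 0]
  present <- lapply(lv, function(l)
    colnames(mat)[colSums(mat[g == l, , drop = FALSE]) > 0])
  names(present) <- lv
  out <- list(shared = intersect(present[[1]], present[[2]]))
  out[[paste0(lv[1], "_only")]] <- setdiff(present[[1]], present[[2]])
  out[[paste0(lv[2], "_only")]] <- setdiff(present[[2]], present[[1]])
  stopifnot(setequal(unlist(out), observed))
  out
}
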