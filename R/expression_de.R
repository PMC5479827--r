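#' Keep genes passing the expression floor
#'
#' A gene is "expressed" when its RPKM strictly exceeds `threshold` in at
#' least one sample; everything else is dropped.
#'
#' @param em an RPKM-mode [expression_matrix].
#' @param threshold strict RPKM bound (default 1).
#' @return The filtered [expression_matrix].
#' @export
expressed_filter <- function(em, threshold = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$mode != "rpkm") stop("expressed_filter expects RPKM mode; see to_rpkm()")
  keep <- apply(em$values, 1L, max) > threshold
  expression_matrix(em$values[keep, , drop = FALSE], mode = "rpkm",
                    annotations = if (!is.null(em$annotations))
                      em$annotations[intersect(rownames(em$values)[keep],
                                               rownames(em$annotations)), ,
                                     drop = FALSE])
}

#' log2 fold change of two group means
#'
#' `log2(mean_num / mean_den)`; antisymmetric under swapping the groups.
#' A zero mean leaves the ratio undefined: callers report the gene with a
#' flag instead of a number.
#'
#' @param mean_num,mean_den group mean expression values, both > 0.
#' @return log2 ratio.
#' @export
log2_fold_change <- function(mean_num, mean_den) {
  if (any(mean_num < 0) || any(mean_den < 0)) stop("means must be >= 0")
  if (any(mean_num == 0) || any(mean_den == 0))
    stop("undefined log2 ratio: zero group mean", call. = FALSE)
  log2(mean_num / mean_den)
}

#' Classify genes as up, down or not significant
#'
#' Inclusive thresholds: `up` when `log2fc >= threshold`, `down` when
#' `log2fc <= -threshold`, otherwise `ns`. The inclusive reading is
#' deliberate: a gene sitting exactly on the boundary (printed log2 ratio
#' 1.00) belongs to the regulated set in the reference panels this package
#' mirrors, so a strict `>` rule would contradict the published counts.
#' `NA` ratios stay `NA`. Boundary comparisons use a 1e-9 absolute
#' tolerance so that decimal inputs whose exact ratio sits on the
#' threshold (a mean ratio of exactly 2) classify deterministically
#' despite floating-point rounding.
#'
#' @param log2fc numeric vector of log2 ratios.
#' @param threshold DE magnitude bound (default 1).
#' @return factor with levels `down`, `ns`, `up`.
#' @export
classify_de <- function(log2fc, threshold = 1.0) {
  eps <- 1e-9
  cls <- ifelse(is.na(log2fc), NA_character_,
                ifelse(log2fc >= threshold - eps, "up",
                       ifelse(log2fc <= -threshold + eps, "down", "ns")))
  factor(cls, levels = c("down", "ns", "up"))
}

#' Group means, log2 fold change and DE class per gene
#'
#' The differential-expression screen: group mean RPKM for the numerator
#' and denominator groups, their log2 ratio, and an inclusive-threshold
#' classification. Genes with a zero group mean get `ratio_defined = FALSE`
#' and an `NA` ratio/class rather than an infinity.
#'
#' @param em an RPKM-mode [expression_matrix] (normally pre-filtered with
#'   [expressed_filter()]).
#' @param groups named two-level factor over the samples.
#' @param numerator,denominator group labels forming the ratio
#'   (`log2(numerator/denominator)`); defaults: first and second level.
#' @param threshold DE magnitude bound (default 1).
#' @return data.frame keyed by gene id: `mean_num`, `mean_den`, `log2fc`,
#'   `ratio_defined`, `expressed`, `class`; attribute `"groups"` records
#'   the labels used.
#' @export
de_table <- function(em, groups, numerator = NULL, denominator = NULL,
                     threshold = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$mode != "rpkm") stop("de_table expects RPKM mode; see to_rpkm()")
  if (is.null(names(groups)))
    names(groups) <- colnames(em$values)
  if (!setequal(names(groups), colnames(em$values)))
    stop("group names must match the matrix samples")
  groups <- factor(as.character(groups[colnames(em$values)]))
  lv <- levels(groups)
  numerator <- numerator %||% lv[1]
  denominator <- denominator %||% lv[2]
  stopifnot(all(c(numerator, denominator) %in% lv))
  mean_num <- rowMeans(em$values[, groups == numerator, drop = FALSE])
  mean_den <- rowMeans(em$values[, groups == denominator, drop = FALSE])
  defined <- mean_num > 0 & mean_den > 0
  log2fc <- rep(NA_real_, nrow(em$values))
  log2fc[defined] <- log2(mean_num[defined] / mean_den[defined])
  out <- data.frame(mean_num = mean_num, mean_den = mean_den,
                    log2fc = log2fc, ratio_defined = defined,
                    expressed = TRUE,
                    class = classify_de(log2fc, threshold))
  rownames(out) <- rownames(em$values)
  attr(out, "groups") <- c(numerator = numerator, denominator = denominator)
  out
}

#' Genes exceeding a high-expression floor in some group
#'
#' Census of strongly expressed genes: those whose larger group-mean RPKM
#' strictly exceeds `floor`, after removing an optional reference gene
#' (e.g. a constitutively dominant one reported separately).
#'
#' @param de a [de_table()] result.
#' @param floor strict group-mean RPKM bound (default 100).
#' @param exclude gene ids to leave out of the census.
#' @return character vector of gene ids.
#' @export
high_expression_report <- function(de, floor = 100.0, exclude = character(0)) {
  genes <- rownames(de)[pmax(de$mean_num, de$mean_den) > floor]
  setdiff(genes, exclude)
}

#' Write a DE table as TSV (symbol, means, log2, class, family)
#' @param de a [de_table()] result.
#' @param path output file.
#' @param annotations optional annotation data.frame keyed by gene id.
#' @export
write_de_table <- function(de, path, annotations = NULL) {
  g <- attr(de, "groups")
  out <- data.frame(gene_id = rownames(de), de,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    for (col in intersect(c("description", "family"), colnames(annotations)))
      out[[col]] <- annotations[[col]][match(out$gene_id, rownames(annotations))]
  }
  names(out)[names(out) == "mean_num"] <- paste0("mean_", g[["numerator"]])
  names(out)[names(out) == "mean_den"] <- paste0("mean_", g[["denominator"]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
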