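#' Construct a gene expression matrix
#'
#' Holds genes x samples expression values either as raw read counts (with
#' per-gene transcript lengths and per-sample mapped-read totals) or as
#' precomputed RPKM, together with per-gene annotations (symbol, description
#' and lectin/cytokine family tag).
#'
#' @param values numeric matrix, genes x samples, with unique dimnames.
#' @param mode `"rpkm"` or `"counts"`.
#' @param lengths named numeric vector of transcript lengths in bp
#'   (required in `"counts"` mode).
#' @param totals named numeric vector of per-sample mapped-read totals
#'   (required in `"counts"` mode).
#' @param annotations optional data.frame keyed by gene id (rownames) with
#'   columns such as `symbol`, `description`, `family`.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, mode = c("rpkm", "counts"),
                              lengths = NULL, totals = NULL,
                              annotations = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (mode == "counts") {
    if (is.null(lengths) || is.null(totals))
      stop("counts mode requires gene lengths and mapped totals")
    lengths <- lengths[rownames(values)]
    totals <- totals[colnames(values)]
    if (any(is.na(lengths)) || any(lengths <= 0))
      stop("every gene needs a positive length_bp")
    if (any(is.na(totals)) || any(totals <= 0))
      stop("every sample needs a positive mapped-read total")
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    annotations <- annotations[intersect(rownames(values), rownames(annotations)), ,
                               drop = FALSE]
  }
  structure(list(values = values, mode = mode, lengths = lengths,
                 totals = totals, annotations = annotations),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Reads-per-kilobase-per-million normalization
#'
#' `rpkm = count / (length_bp/1000) / (mapped_total/1e6)`: read counts
#' normalized for transcript length (kb) and sequencing depth (millions of
#' mapped reads). Doubling every count together with the mapped total leaves
#' the value unchanged.
#'
#' @param count non-negative read count(s).
#' @param length_bp transcript length(s) in base pairs, > 0.
#' @param mapped_total mapped reads in the sample, > 0.
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, length_bp, mapped_total) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  if (any(mapped_total <= 0)) stop("mapped_total must be > 0")
  count / (length_bp / 1000) / (mapped_total / 1e6)
}

#' Convert a counts-mode expression matrix to RPKM mode
#' @param em an [expression_matrix].
#' @return An RPKM-mode [expression_matrix] with the same genes, samples and
#'   annotations.
#' @export
to_rpkm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$mode == "rpkm") return(em)
  rpkm <- sweep(em$values / (em$lengths / 1000), 2L, em$totals / 1e6, "/")
  expression_matrix(rpkm, mode = "rpkm", annotations = em$annotations)
}

#' Write an expression matrix as TSV
#'
#' Rows are genes, columns samples; counts mode appends a `length_bp` column
#' and records mapped totals in a `#mapped_total:` header comment.
#' @param em an [expression_matrix].
#' @param path output file.
#' @export
write_expression <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (em$mode == "counts") {
    writeLines(paste0("#mapped_total:",
                      paste(colnames(em$values), em$totals,
                            sep = "=", collapse = "\t")), con)
    df <- data.frame(gene_id = rownames(em$values), em$values,
                     length_bp = em$lengths,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene_id = rownames(em$values), em$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#' @param path expression TSV.
#' @param annotations optional annotation data.frame keyed by gene id.
#' @return An [expression_matrix] (mode inferred from the file).
#' @export
read_expression <- function(path, annotations = NULL) {
  first <- readLines(path, n = 1L)
  totals <- NULL
  skip <- 0L
  if (startsWith(first, "#mapped_total:")) {
    skip <- 1L
    kv <- strsplit(strsplit(sub("^#mapped_total:", "", first), "\t")[[1]], "=")
    totals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                              vapply(kv, `[`, "", 1L))
  }
  df <- utils::read.delim(path, check.names = FALSE, skip = skip)
  sample_cols <- setdiff(colnames(df), c("gene_id", "length_bp"))
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(values) <- df$gene_id
  if ("length_bp" %in% colnames(df)) {
    expression_matrix(values, mode = "counts",
                      lengths = stats::setNames(df$length_bp, df$gene_id),
                      totals = totals, annotations = annotations)
  } else {
    expression_matrix(values, mode = "rpkm", annotations = annotations)
  }
}

#' Restrict an expression matrix to a family tag or explicit gene list
#'
#' @param em an [expression_matrix] with annotations carrying a `family`
#'   column (for tag subsetting).
#' @param family family tag, e.g. `"galectin"`, `"CLR"`, `"siglec"`.
#' @param genes explicit gene id vector (used instead of `family` if given;
#'   an empty vector yields an empty matrix).
#' @return The restricted [expression_matrix]; annotations preserved.
#' @export
subset_family <- function(em, family = NULL, genes = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(genes)) {
    if (is.null(family)) stop("give either a family tag or a gene list")
    if (is.null(em$annotations) || !"family" %in% colnames(em$annotations))
      stop("no family annotations present")
    if (!family %in% em$annotations$family)
      stop("unknown family tag: ", family)
    genes <- rownames(em$annotations)[em$annotations$family == family]
  }
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  keep <- rownames(em$values) %in% genes
  expression_matrix(em$values[keep, , drop = FALSE], mode = em$mode,
                    lengths = em$lengths[keep], totals = em$totals,
                    annotations = if (!is.null(em$annotations))
                      em$annotations[intersect(genes, rownames(em$annotations)), ,
                                     drop = FALSE])
}

#' Bundled goat rumen epithelium reference panels
#'
#' Two small group-mean RPKM tables bundled with the package: the expressed
#' lectin panel (35 genes across the C-type lectin, galectin and siglec
#' families) and a differential cytokine/retinoic-acid-enzyme panel, each
#' with columns `symbol`, `description`, `mc_rpkm`, `lc_rpkm` (group-mean
#' RPKM under a 35% vs 10% dietary-concentrate contrast), the published
#' rounded `log2_printed`, and `family`. Rows of the lectin panel whose
#' printed log2 value is arithmetically inconsistent with the printed group
#' means are flagged `log2_consistent = FALSE` and carry no analytic weight.
#'
#' @param which `"lectin"` or `"cytokine"`.
#' @return data.frame keyed by `symbol`.
#' @export
reference_panel <- function(which = c("lectin", "cytokine")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(which, "_panel_rpkm.tsv"),
                      package = "rumilink", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- df$symbol
  df$log2_consistent <-
    abs(round(log2(df$mc_rpkm / df$lc_rpkm), 2) - df$log2_printed) <= 0.0101
  df
}

#' Load a reference panel as a two-sample expression matrix
#'
#' Treats the two group-mean columns as one pseudo-sample per group, which is
#' the resolution at which the bundled panels were published.
#' @param which `"lectin"` or `"cytokine"`.
#' @return list with `em` (an [expression_matrix] of the group means) and
#'   `groups` (named factor `MC`/`LC`).
#' @export
reference_panel_matrix <- function(which = c("lectin", "cytokine")) {
  df <- reference_panel(which)
  values <- as.matrix(df[, c("mc_rpkm", "lc_rpkm")])
  dimnames(values) <- list(df$symbol, c("MC", "LC"))
  ann <- df[, c("symbol", "description", "family")]
  list(em = expression_matrix(values, mode = "rpkm", annotations = ann),
       groups = stats::setNames(factor(c("MC", "LC"), levels = c("MC", "LC")),
                                c("MC", "LC")))
}
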