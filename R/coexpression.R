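#' Build a gene-gene Spearman co-expression network
#'
#' All gene pairs of an (expressed) RPKM matrix are scored by Spearman rho
#' and a permutation p-value; an undirected edge is kept when
#' `|rho| > rho_min` and `p < p_max`. With six samples and two-sided exact
#' p-values, that joint rule is equivalent to `|rho| >= 0.886`: the exact p
#' has a hard floor of `2/720` and the 0.05 quantile of `|rho*|` sits just
#' below 0.886. Absolute rho is used so strong negative co-expression is
#' kept as a (sign-annotated) edge. Genes with constant expression are
#' excluded with a warning; gene pairs with tied values fall back to a
#' seeded Monte Carlo permutation p.
#'
#' @param em an RPKM-mode [expression_matrix] of expressed genes (apply
#'   [expressed_filter()] first).
#' @param rho_min strict absolute-rho bound (default 0.8).
#' @param p_max strict p bound (default 0.05).
#' @param seeds optional character vector of seed genes (stored on the
#'   network; must be present in the matrix).
#' @param alternative sidedness of the permutation p (default two-sided).
#' @param n_mc,rng_seed Monte Carlo fallback settings for tied pairs.
#' @return An object of class `"coexpression_network"`: list with `edges`
#'   (data.frame `gene_a`, `gene_b`, `rho`, `p`, `sign`), `genes`, `seeds`,
#'   `thresholds`, `degree` (named census) and `graph` (igraph).
#' @export
build_network <- function(em, rho_min = 0.8, p_max = 0.05, seeds = NULL,
                          alternative = "two.sided",
                          n_mc = 1e5, rng_seed = 1L) {
  stopifnot(inherits(em, "expression_matrix"))
  values <- em$values
  n <- ncol(values)
  if (n < 3) stop("need at least 3 samples for a correlation network")
  constant <- apply(values, 1L, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning("excluding ", sum(constant),
            " gene(s) with constant expression: correlation undefined")
    values <- values[!constant, , drop = FALSE]
  }
  genes <- rownames(values)
  if (!is.null(seeds)) {
    missing <- setdiff(seeds, genes)
    if (length(missing))
      stop("seed gene(s) not in the matrix: ", paste(missing, collapse = ", "))
  }

  rho_mat <- stats::cor(t(values), method = "spearman")
  tied <- apply(values, 1L, anyDuplicated) > 0
  pfun <- spearman_p_fun(n, alternative)

  pairs <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[pairs]
  # cheap pre-screen: p is monotone in |rho|, so only candidate edges need p
  cand <- abs(rho) > rho_min
  p <- rep(NA_real_, length(rho))
  idx <- which(cand)
  if (length(idx)) {
    clean <- !(tied[pairs[idx, 1]] | tied[pairs[idx, 2]])
    p[idx[clean]] <- pfun(rho[idx[clean]])
    for (k in idx[!clean]) {
      p[k] <- spearman_test(values[pairs[k, 1], ], values[pairs[k, 2], ],
                            alternative = alternative, n_mc = n_mc,
                            rng_seed = rng_seed)$p
    }
  }
  keep <- cand & !is.na(p) & p < p_max
  edges <- data.frame(gene_a = genes[pairs[keep, 1]],
                      gene_b = genes[pairs[keep, 2]],
                      rho = rho[keep], p = p[keep],
                      sign = ifelse(rho[keep] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  degree <- igraph::degree(g)
  structure(list(edges = edges, genes = genes, seeds = seeds,
                 thresholds = list(rho_min = rho_min, p_max = p_max,
                                   alternative = alternative),
                 degree = degree, graph = g),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, %d edges (|rho| > %g, p < %g)\n",
              length(x$genes), nrow(x$edges),
              x$thresholds$rho_min, x$thresholds$p_max))
  invisible(x)
}

#' First neighbors of seed genes on the network
#'
#' @param network a [build_network()] result.
#' @param seeds seed gene ids (defaults to the network's stored seeds).
#' @return named list: per seed, the character vector of adjacent genes.
#' @export
first_neighbors <- function(network, seeds = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  seeds <- seeds %||% network$seeds
  if (is.null(seeds)) stop("no seed genes given")
  missing <- setdiff(seeds, network$genes)
  if (length(missing))
    stop("unknown seed(s): ", paste(missing, collapse = ", "))
  e <- network$edges
  out <- lapply(seeds, function(s)
    sort(unique(c(e$gene_b[e$gene_a == s], e$gene_a[e$gene_b == s]))))
  names(out) <- seeds
  out
}

#' Differentially expressed first neighbors of the seeds
#'
#' Filters seed neighborhoods to neighbors whose DE class is not `"ns"`,
#' keeping the correlation sign (the direction of co-expression with the
#' seed) next to the neighbor's regulation direction.
#'
#' @param network a [build_network()] result.
#' @param seeds seed gene ids (defaults to stored seeds).
#' @param de a [de_table()] result covering the neighbor genes.
#' @return data.frame `seed`, `neighbor`, `rho`, `sign`, `neighbor_class`.
#' @export
differential_neighbors <- function(network, seeds = NULL, de) {
  stopifnot(inherits(network, "coexpression_network"))
  seeds <- seeds %||% network$seeds %||% character(0)
  if (length(seeds) == 0)
    return(data.frame(seed = character(0), neighbor = character(0),
                      rho = numeric(0), sign = character(0),
                      neighbor_class = character(0)))
  nb <- first_neighbors(network, seeds)
  e <- network$edges
  rows <- do.call(rbind, lapply(seeds, function(s) {
    if (!length(nb[[s]])) return(NULL)
    sel <- (e$gene_a == s & e$gene_b %in% nb[[s]]) |
      (e$gene_b == s & e$gene_a %in% nb[[s]])
    sub <- e[sel, , drop = FALSE]
    neighbor <- ifelse(sub$gene_a == s, sub$gene_b, sub$gene_a)
    data.frame(seed = s, neighbor = neighbor, rho = sub$rho,
               sign = sub$sign, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(seed = character(0), neighbor = character(0),
                      rho = numeric(0), sign = character(0),
                      neighbor_class = character(0)))
  cls <- de$class[match(rows$neighbor, rownames(de))]
  rows$neighbor_class <- as.character(cls)
  rows <- rows[!is.na(rows$neighbor_class) & rows$neighbor_class != "ns", ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Aggregate differential neighbors by a user-supplied pathway map
#'
#' The pathway map externalizes any database lookup: it is a plain
#' two-column table (`gene`, `pathway`). Genes absent from the map are
#' counted under an explicit `"unmapped"` bin, never dropped; a gene mapped
#' to several pathways appears in each.
#'
#' @param table a [differential_neighbors()] table.
#' @param pathway_map data.frame with columns `gene`, `pathway`.
#' @return data.frame `pathway`, `n_genes`, `genes` (comma-joined),
#'   `seeds` (comma-joined seed genes whose neighborhoods hit the pathway).
#' @export
aggregate_by_pathway <- function(table, pathway_map) {
  if (!all(c("gene", "pathway") %in% colnames(pathway_map)))
    stop("pathway map needs columns gene, pathway")
  if (nrow(table) == 0)
    return(data.frame(pathway = character(0), n_genes = integer(0),
                      genes = character(0), seeds = character(0)))
  hit <- merge(table, pathway_map, by.x = "neighbor", by.y = "gene",
               all.x = TRUE)
  hit$pathway[is.na(hit$pathway)] <- "unmapped"
  split_rows <- split(hit, hit$pathway)
  out <- do.call(rbind, lapply(names(split_rows), function(pw) {
    sub <- split_rows[[pw]]
    genes <- sort(unique(sub$neighbor))
    data.frame(pathway = pw, n_genes = length(genes),
               genes = paste(genes, collapse = ","),
               seeds = paste(sort(unique(sub$seed)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$pathway), , drop = FALSE]
}

#' Write a network in GraphML for external viewers
#' @param network a [build_network()] result.
#' @param path output `.graphml` file.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Write network edges as TSV
#' @param network a [build_network()] result.
#' @param path output file.
#' @export
write_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
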