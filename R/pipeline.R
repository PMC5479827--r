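#' Pipeline configuration
#'
#' Single source of every threshold of the end-to-end analysis plus the
#' input file paths. Thresholds default to the canonical cut-offs of the
#' study design this package models: OTU count > 3, detectability >= 1%,
#' expressed RPKM > 1, |log2FC| >= 1, network |rho| > 0.8 with p < 0.05,
#' integration |rho| >= 0.6 with p <= 0.05.
#'
#' @param otu_table path to the OTU TSV ([write_otu_table()] format).
#' @param metadata path to the sample metadata TSV.
#' @param expression path to the expression TSV (RPKM, or counts+lengths).
#' @param seed_genes path to a plain-text seed-gene list (one id per
#'   line), or `NULL` to use the differentially expressed genes.
#' @param pathway_map optional path to a two-column TSV (`gene`,
#'   `pathway`).
#' @param min_count,detectable,rpkm_expressed,de_log2,net_rho,net_p,integr_rho,integr_p
#'   stage thresholds (see above).
#' @param numerator,denominator group labels forming the fold-change ratio.
#' @param alternative sidedness of permutation p-values.
#' @param signed_rho,weighted_centroids,log_constraints integration options.
#' @param rng_seed seed for every Monte Carlo fallback.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(otu_table, metadata, expression,
                            seed_genes = NULL, pathway_map = NULL,
                            min_count = 3, detectable = 0.01,
                            rpkm_expressed = 1.0, de_log2 = 1.0,
                            net_rho = 0.8, net_p = 0.05,
                            integr_rho = 0.6, integr_p = 0.05,
                            numerator = "MC", denominator = "LC",
                            alternative = "two.sided",
                            signed_rho = FALSE,
                            weighted_centroids = FALSE,
                            log_constraints = FALSE,
                            rng_seed = 1L) {
  cfg <- list(paths = list(otu_table = otu_table, metadata = metadata,
                           expression = expression, seed_genes = seed_genes,
                           pathway_map = pathway_map),
              thresholds = list(min_count = min_count, detectable = detectable,
                                rpkm_expressed = rpkm_expressed,
                                de_log2 = de_log2, net_rho = net_rho,
                                net_p = net_p, integr_rho = integr_rho,
                                integr_p = integr_p),
              options = list(numerator = numerator, denominator = denominator,
                             alternative = alternative,
                             signed_rho = signed_rho,
                             weighted_centroids = weighted_centroids,
                             log_constraints = log_constraints,
                             rng_seed = as.integer(rng_seed)))
  if (any(vapply(cfg$thresholds, function(t) t < 0, TRUE)))
    stop("thresholds must be non-negative")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  needed <- config$paths[!vapply(config$paths, is.null, TRUE)]
  missing <- needed[!vapply(needed, file.exists, TRUE)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(unlist(missing), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

stage_log <- function(stage, n_in, n_out, t0) {
  message(sprintf("[%s] n_in=%d n_out=%d elapsed=%.2fs",
                  stage, n_in, n_out,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline: abundance, expression, network, integration
#'
#' Executes all stages in order, writes every module output plus a run
#' manifest into `out_dir`, and returns the in-memory results. Fully
#' deterministic given the config: re-running writes byte-identical files
#' (the manifest deliberately carries no wall-clock fields).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return list with per-stage results (`abundance`, `expression`,
#'   `network`, `integration`) and the `manifest`.
#' @export
run_all <- function(config, out_dir) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  th <- config$thresholds
  op <- config$options
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  counts_rec <- list()

  ## ---- abundance ----
  t0 <- as.numeric(Sys.time())
  otu <- read_otu_table(config$paths$otu_table, config$paths$metadata)
  filtered <- filter_min_count(otu, th$min_count)
  profile <- to_relative(filtered)
  phylum <- to_relative(aggregate_at_rank(filtered, "phylum"))
  genus <- to_relative(aggregate_at_rank(filtered, "genus"))
  detectable <- detectable_filter(profile, th$detectable)
  h <- shannon_per_sample(profile)
  bc <- bray_curtis(profile)
  ano <- anosim(bc, filtered$groups, rng_seed = op$rng_seed)
  venn <- shared_taxa(filtered, rank = "phylum")
  counts_rec$abundance <- c(n_in = n_otus(otu), n_out = n_otus(filtered))
  stage_log("abundance", n_otus(otu), n_otus(filtered), t0)
  utils::write.table(data.frame(sample = names(h), shannon = h),
                     file.path(out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(taxon = colnames(phylum$abund),
                                t(phylum$abund)),
                     file.path(out_dir, "phylum_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ano, file.path(out_dir, "anosim.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- expression ----
  t0 <- as.numeric(Sys.time())
  em <- read_expression(config$paths$expression)
  if (em$mode == "counts") em <- to_rpkm(em)
  if (!setequal(colnames(em$values), names(filtered$groups)))
    stop("expression and OTU samples differ")
  expressed <- expressed_filter(em, th$rpkm_expressed)
  de <- de_table(expressed, filtered$groups[colnames(expressed$values)],
                 numerator = op$numerator, denominator = op$denominator,
                 threshold = th$de_log2)
  counts_rec$expression <- c(n_in = nrow(em$values),
                             n_out = nrow(expressed$values))
  stage_log("expression", nrow(em$values), nrow(expressed$values), t0)
  write_de_table(de, file.path(out_dir, "de_table.tsv"),
                 annotations = expressed$annotations)

  ## ---- coexpression ----
  t0 <- as.numeric(Sys.time())
  de_genes <- rownames(de)[!is.na(de$class) & de$class != "ns"]
  seeds <- if (!is.null(config$paths$seed_genes)) {
    listed <- readLines(config$paths$seed_genes)
    listed <- listed[nzchar(listed)]
    intersect(listed, rownames(expressed$values))
  } else de_genes
  net <- withCallingHandlers(
    build_network(expressed, rho_min = th$net_rho, p_max = th$net_p,
                  seeds = seeds, alternative = op$alternative,
                  rng_seed = op$rng_seed),
    warning = function(w) { note("network: %s", conditionMessage(w))
      invokeRestart("muffleWarning") })
  diff_nb <- differential_neighbors(net, seeds, de)
  pathways <- if (!is.null(config$paths$pathway_map))
    aggregate_by_pathway(diff_nb,
                         utils::read.delim(config$paths$pathway_map))
  counts_rec$coexpression <- c(n_in = nrow(expressed$values),
                               n_out = nrow(net$edges))
  stage_log("network", nrow(expressed$values), nrow(net$edges), t0)
  write_edges(net, file.path(out_dir, "edges.tsv"))
  write_graphml(net, file.path(out_dir, "network.graphml"))
  utils::write.table(diff_nb, file.path(out_dir, "differential_neighbors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathways))
    utils::write.table(pathways, file.path(out_dir, "pathway_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- integration ----
  t0 <- as.numeric(Sys.time())
  integ <- withCallingHandlers(
    run_integration(profile, expressed, seeds,
                    rho_min = th$integr_rho, p_max = th$integr_p,
                    signed_rho = op$signed_rho,
                    alternative = op$alternative,
                    rng_seed = op$rng_seed,
                    log_constraints = op$log_constraints,
                    weighted_centroids = op$weighted_centroids),
    warning = function(w) { note("integration: %s", conditionMessage(w))
      invokeRestart("muffleWarning") })
  counts_rec$integration <- c(n_in = integ$n_total, n_out = integ$n_retained)
  stage_log("integration", integ$n_total, integ$n_retained, t0)
  utils::write.table(integ$filter$correlations,
                     file.path(out_dir, "retained_otus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (integ$status == "ok") {
    fit <- integ$cca
    jsonlite::write_json(
      list(eigenvalues = as.list(fit$eigenvalues),
           unconstrained_eigenvalues = as.list(fit$unconstrained_eigenvalues),
           total_inertia = fit$total_inertia,
           scaling = fit$scaling),
      file.path(out_dir, "cca_inertia.json"), auto_unbox = TRUE, digits = NA)
    for (nm in c("species_scores", "site_scores_lc", "site_scores_wa",
                 "biplot_scores")) {
      utils::write.table(data.frame(id = rownames(fit[[nm]]), fit[[nm]]),
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(integ$centroids))
      utils::write.table(data.frame(genus = rownames(integ$centroids),
                                    integ$centroids),
                         file.path(out_dir, "genus_centroids.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines("status: empty (no OTU passed the correlation screen)",
               file.path(out_dir, "integration_status.txt"))
  }

  ## ---- manifest ----
  manifest <- list(
    package_version = as.character(utils::packageVersion("rumilink")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(config$paths[
      !vapply(config$paths, is.null, TRUE)]))),
    stage_counts = counts_rec,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(abundance = list(table = filtered, profile = profile,
                                  phylum = phylum, genus = genus,
                                  detectable = detectable,
                                  shannon = h, anosim = ano, venn = venn),
                 expression = list(em = expressed, de = de),
                 network = list(net = net, differential_neighbors = diff_nb,
                                pathways = pathways),
                 integration = integ,
                 manifest = manifest))
}

#' Generate the demo fixture bundle and a ready-to-run configuration
#'
#' Writes the default synthetic dataset (or one from a supplied config),
#' its ground truth, and a `config.yaml` pointing at the files, so the
#' whole pipeline can be exercised without any external data.
#'
#' @param dir output directory.
#' @param config a [synthetic_config()] (default: the standard preset).
#' @return list with `files` (fixture paths), `config_path`, `truth`.
#' @export
make_demo <- function(dir, config = synthetic_config()) {
  otu <- generate_otu_counts(config)
  gen <- generate_expression(config)
  files <- write_fixtures(otu, gen$em, gen$truth, dir)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(otu_table = files[["otu_table"]],
                        metadata = files[["metadata"]],
                        expression = files[["expression"]],
                        rng_seed = config$rng_seed),
                   config_path)
  list(files = files, config_path = config_path, truth = gen$truth)
}
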