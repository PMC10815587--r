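#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the study defaults:
#' 100 kb site-centered scoring window, top 10% cis / top 5% trans
#' percentile thresholds, minimum run of 16 consecutive positive sites,
#' DE thresholds FDR < 0.05 and |logFC| > 0.5, k = 4 kinetic clusters.
#' The seed is mandatory: every stochastic stage derives from it.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed.
#' @param scenario A [synthetic_scenario()]; its own seed is overridden
#'   by `seed`.
#' @param window_bp,top_frac_cis,top_frac_trans,min_run Domain-caller
#'   tunables.
#' @param alpha,lfc_min,k Expression tunables.
#' @param fdr_permutations Permutations for [estimate_fdr()] (default 50).
#' @param condition 4C condition scored for domains (default `"0h"`).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed,
                            scenario = synthetic_scenario(seed = seed),
                            window_bp = 1e5, top_frac_cis = 0.10,
                            top_frac_trans = 0.05, min_run = 16L,
                            alpha = 0.05, lfc_min = 0.5, k = 4L,
                            fdr_permutations = 50L, condition = "0h") {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(
    as.integer(seed))))
    stop("seed is mandatory and must be an integer")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              scenario = scenario, window_bp = window_bp,
              top_frac_cis = top_frac_cis,
              top_frac_trans = top_frac_trans, min_run = as.integer(min_run),
              alpha = alpha, lfc_min = lfc_min, k = as.integer(k),
              fdr_permutations = as.integer(fdr_permutations),
              condition = condition)
  for (tf in c("top_frac_cis", "top_frac_trans"))
    if (!(cfg[[tf]] > 0 && cfg[[tf]] < 1))
      stop(tf, " must be in (0, 1), got ", cfg[[tf]])
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (cfg$window_bp <= 0) stop("window_bp must be > 0")
  if (cfg$min_run < 1L) stop("min_run must be >= 1")
  if (cfg$k < 1L) stop("k must be >= 1")
  cfg$scenario$seed <- cfg$seed
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full synthetic-to-integration pipeline
#'
#' Stages, in dependency order: simulate (fragment map, 4C counts, genes,
#' expression, ChIP) -> contact domains (cis and trans, with permutation
#' FDR) -> differential expression and kinetic clustering -> spatial
#' integration (gene density, cluster enrichment, ChIP dynamics).  Every
#' artifact is written under `config$out_dir` with a JSON sidecar; the
#' returned manifest lists all outputs with md5 checksums and re-running
#' with an identical config yields identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), also written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[spatialcontact] ", ...)
  out <- function(f) file.path(config$out_dir, f)
  paths <- character(0)
  keep <- function(p) { paths[[length(paths) + 1L]] <<- p; p }
  sc <- config$scenario

  say("stage synth: fragment map + 4C + genes + expression + ChIP")
  fm <- simulate_fragment_map(sc)
  write_fragment_map(fm, keep(out("fragments.bed")))
  profiles <- simulate_4c_counts(sc, fm, conditions = config$condition)
  profile <- profiles[[config$condition]]
  write_site_counts(profile, keep(out("counts_4c.tsv")))
  genes <- simulate_genes(sc, fm)
  write_gene_table(genes, keep(out("genes.tsv")))
  expr <- simulate_expression(sc, genes)
  write_expression_table(expr, keep(out("expression_counts.tsv")),
                         keep(out("samples.tsv")))
  chip <- simulate_chip(sc, fm)
  for (tp in names(chip)) {
    write_bedgraph(chip[[tp]], keep(out(sprintf("chip_ip_%s.bedGraph", tp))),
                   "ip")
    write_bedgraph(chip[[tp]],
                   keep(out(sprintf("chip_input_%s.bedGraph", tp))),
                   "input")
  }

  say("stage domains: window p-scores, thresholds, run-length calling")
  dom_sets <- list(); fdr <- list()
  for (scope in c("cis", "trans")) {
    tf <- if (scope == "cis") config$top_frac_cis else config$top_frac_trans
    track <- threshold_sites(
      window_pscore(profile, fm, config$window_bp, scope), tf)
    write_bedgraph(
      data.frame(chrom = track$chrom, start = track$pos,
                 end = track$pos + 1, p_score = track$p_score),
      keep(out(sprintf("pscore_%s.bedGraph", scope))), "p_score")
    doms <- call_domains(track, fm, config$min_run)
    fdr[[scope]] <- estimate_fdr(profile, fm, config$window_bp, scope, tf,
                                 config$fdr_permutations,
                                 seed = config$seed)
    write_domains_bed(doms, keep(out(sprintf("domains_%s.bed", scope))))
    write_sidecar(out(sprintf("domains_%s.bed", scope)),
                  params = c(attr(doms, "params"),
                             list(achieved_fdr = fdr[[scope]]$fdr,
                                  condition = config$condition)),
                  inputs = c(out("counts_4c.tsv"), out("fragments.bed")))
    dom_sets[[scope]] <- doms
  }

  say("stage expression: DE contrasts + kinetic clustering")
  de <- de_all_contrasts(expr, alpha = config$alpha,
                         lfc_min = config$lfc_min)
  utils::write.table(de, keep(out("de_table.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de_genes <- unique(de$gene_id[de$de])
  clusters <- NULL
  if (length(de_genes) >= config$k) {
    cl <- cluster_kinetics(expr, de_genes, k = config$k,
                           seed = config$seed)
    clusters <- data.frame(gene_id = names(cl$labels),
                           cluster = as.character(cl$labels))
    utils::write.table(
      data.frame(cluster = rownames(cl$centers), cl$centers,
                 check.names = FALSE),
      keep(out("cluster_profiles.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else {
    say("fewer DE genes than k; clustering skipped")
    clusters <- data.frame(gene_id = character(0), cluster = character(0))
  }
  utils::write.table(clusters, keep(out("clusters.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage integrate: gene density, enrichment, ChIP dynamics")
  genome_bp <- sum(fm$chrom_lengths)
  dens <- lapply(dom_sets, gene_density, genes = genes,
                 genome_size_bp = genome_bp)
  dens_df <- data.frame(
    domain_set = names(dens),
    density_in_domains = vapply(dens, `[[`, 0, "density_in_domains"),
    density_genome = vapply(dens, `[[`, 0, "density_genome"))
  utils::write.table(dens_df, keep(out("gene_density.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes_cl <- genes
  if (nrow(clusters)) {
    called <- match(genes_cl$gene_id, clusters$gene_id)
    genes_cl$cluster <- ifelse(is.na(called), "stable",
                               clusters$cluster[called])
  }
  enr <- cluster_enrichment(dom_sets, genes_cl)
  utils::write.table(
    data.frame(cluster = rownames(enr$enrichment), enr$enrichment,
               check.names = FALSE),
    keep(out("cluster_enrichment.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(cluster = rownames(enr$log2), enr$log2,
               check.names = FALSE),
    keep(out("cluster_enrichment_log2.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  comp <- scenario_compartments(sc, fm)
  comp_sets <- split(comp[c("chrom", "start", "end")], comp$label)
  chip_tab <- chip_dynamics_table(chip, comp_sets)
  utils::write.table(chip_tab, keep(out("chip_ratios.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg_rec <- config
  cfg_rec$scenario <- NULL    # scenario recorded via seed + defaults
  manifest <- list(
    tool = "spatialcontact",
    version = as.character(utils::packageVersion("spatialcontact")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg_rec),
    achieved_fdr = lapply(fdr, `[[`, "fdr"),
    outputs = lapply(stats::setNames(paths, basename(unlist(paths))),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
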