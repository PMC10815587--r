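#' @importFrom methods is
NULL

domain_union_gr <- function(domains) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    domains$chrom, IRanges::IRanges(domains$start + 1, domains$end)))
}

gene_tss <- function(genes) {
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(tss + 1, width = 1))
}

#' Gene density inside contact domains vs. the genome
#'
#' Density is genes per Mb: genes whose TSS (start on `+`, `end - 1` on
#' `-`) falls in the domain union, divided by the union length, against
#' the genome-wide control of all genes over the genome length.
#'
#' @param domains A [call_domains()] set or any data.frame with `chrom`,
#'   `start`, `end` (half-open).
#' @param genes Gene table with `chrom`, `start`, `end`, `strand`.
#' @param genome_size_bp Total assembly length in bp.
#' @return List `density_in_domains`, `density_genome` (genes/Mb),
#'   `n_in_domains`, `domain_mb`.  Empty domain set gives `NA` for the
#'   domain density.
#' @export
gene_density <- function(domains, genes, genome_size_bp) {
  n_genes <- nrow(genes)
  dens_genome <- if (n_genes == 0) 0 else n_genes / (genome_size_bp / 1e6)
  if (nrow(domains) == 0L) {
    message("empty domain set; domain gene density not applicable")
    return(list(density_in_domains = NA_real_,
                density_genome = dens_genome, n_in_domains = 0L,
                domain_mb = 0))
  }
  u <- domain_union_gr(domains)
  mb <- sum(BiocGenerics::width(u)) / 1e6
  n_in <- if (n_genes == 0) 0L
          else sum(IRanges::overlapsAny(gene_tss(genes), u))
  list(density_in_domains = n_in / mb, density_genome = dens_genome,
       n_in_domains = n_in, domain_mb = mb)
}

#' Relative enrichment of expression clusters in contact domains
#'
#' For cluster `c` and bait `b`:
#' `enrichment = (fraction of cluster-c genes with TSS in b's domain
#' union) / (fraction of universe genes with TSS in b's domain union)`.
#' The universe is every gene in `genes` (clustered plus stable), i.e.
#' the expressed universe on which clusters are defined.  A one-sided
#' hypergeometric p-value for over-representation accompanies each cell.
#'
#' @param domain_sets Named list of domain data.frames, one per bait.
#' @param genes Gene table with `chrom`, `start`, `end`, `strand`,
#'   `cluster` (levels `1`..`4` and `stable`).
#' @param clusters Cluster labels to tabulate (default `1:4`).
#' @return List of matrices (clusters x baits): `enrichment`, `log2`
#'   (log2 enrichment), `p_hyper`, plus `frac_universe` per bait.  Cells
#'   with no universe gene in the domains are `NA`.
#' @export
cluster_enrichment <- function(domain_sets, genes,
                               clusters = as.character(1:4)) {
  stopifnot(is.list(domain_sets), !is.null(names(domain_sets)))
  baits <- names(domain_sets)
  tss <- gene_tss(genes)
  n_univ <- nrow(genes)
  enr <- p_hyp <- matrix(NA_real_, length(clusters), length(baits),
                         dimnames = list(clusters, baits))
  frac_univ <- stats::setNames(numeric(length(baits)), baits)
  for (b in baits) {
    if (nrow(domain_sets[[b]]) == 0L) { frac_univ[b] <- NA; next }
    u <- domain_union_gr(domain_sets[[b]])
    inside <- IRanges::overlapsAny(tss, u)
    m_in <- sum(inside)
    frac_univ[b] <- m_in / n_univ
    if (m_in == 0L) next   # denominator fraction 0: cells not applicable
    for (cl in clusters) {
      sel <- genes$cluster == cl
      n_c <- sum(sel)
      if (n_c == 0L) next
      x <- sum(inside & sel)
      enr[cl, b] <- (x / n_c) / (m_in / n_univ)
      p_hyp[cl, b] <- stats::phyper(x - 1, m_in, n_univ - m_in, n_c,
                                    lower.tail = FALSE)
    }
  }
  list(enrichment = enr, log2 = log2(enr), p_hyper = p_hyp,
       frac_universe = frac_univ)
}

#' ChIP IP/input signal over a domain set
#'
#' Selects the bins whose overlap with the domain union is at least half
#' the bin width and returns `sum(IP) / sum(input)` over them, optionally
#' after dividing each track by its library size (default on, so the
#' ratio is comparable across timepoints with different depths).
#'
#' @param track A `BinnedChipTrack` (see [simulate_chip()]) or data.frame
#'   with `chrom`, `start`, `end`, `ip`, `input`.
#' @param domains Domain data.frame (`chrom`, `start`, `end`).
#' @param scale_libsize Divide IP and input by their library sizes first
#'   (default TRUE).
#' @param min_bin_overlap Minimum fraction of the bin covered by the
#'   domain union (default 0.5).
#' @return List `ratio`, `n_bins`, `timepoint`.
#' @export
chip_signal_in_domains <- function(track, domains, scale_libsize = TRUE,
                                   min_bin_overlap = 0.5) {
  if (nrow(domains) == 0L) stop("empty domain set")
  u <- domain_union_gr(domains)
  bins <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1, track$end))
  ov <- GenomicRanges::findOverlaps(bins, u)
  covered <- rep(0, length(bins))
  if (length(ov)) {
    w <- BiocGenerics::width(IRanges::pintersect(
      bins[S4Vectors::queryHits(ov)], u[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  sel <- covered >= min_bin_overlap * BiocGenerics::width(bins)
  ip <- sum(track$ip[sel]); inp <- sum(track$input[sel])
  if (inp == 0)
    stop("zero input reads in domain set",
         if (!is.null(attr(track, "timepoint")))
           paste0(" at timepoint ", attr(track, "timepoint")))
  if (scale_libsize) {
    ip_lib <- attr(track, "ip_library_size") %||% sum(track$ip)
    in_lib <- attr(track, "input_library_size") %||% sum(track$input)
    ratio <- (ip / ip_lib) / (inp / in_lib)
  } else {
    ratio <- ip / inp
  }
  list(ratio = ratio, n_bins = sum(sel),
       timepoint = attr(track, "timepoint"))
}

#' ChIP IP/input time series over several domain sets
#'
#' Applies [chip_signal_in_domains()] to every (domain set, timepoint)
#' pair, yielding the repair-kinetics table plotted per bait environment
#' in the study design.
#'
#' @param tracks Named list of `BinnedChipTrack`s over timepoints.
#' @param domain_sets Named list of domain data.frames.
#' @inheritParams chip_signal_in_domains
#' @return data.frame `domain_set`, `timepoint`, `ratio`, `n_bins`.
#' @export
chip_dynamics_table <- function(tracks, domain_sets, scale_libsize = TRUE,
                                min_bin_overlap = 0.5) {
  out <- list()
  for (ds in names(domain_sets)) {
    for (tp in names(tracks)) {
      r <- chip_signal_in_domains(tracks[[tp]], domain_sets[[ds]],
                                  scale_libsize, min_bin_overlap)
      out[[length(out) + 1L]] <- data.frame(
        domain_set = ds, timepoint = tp, ratio = r$ratio,
        n_bins = r$n_bins, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
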