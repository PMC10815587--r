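# Readers and writers for the plain-text interchange formats.  All
# genomic files are 0-based half-open, sorted by (chrom, start).

#' Write per-site counts as TSV (chrom, site_pos, count)
#' @param profile A [site_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(profile, path) {
  utils::write.table(
    data.frame(chrom = profile$chrom, site_pos = profile$pos,
               count = profile$count),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-site counts and align them to a fragment map
#' @param path TSV with header `chrom`, `site_pos`, `count`.
#' @param fragmap The [fragment_map()] the counts live on.
#' @param bait,bait_id,condition Passed to [site_profile()].
#' @return A [site_profile()].
#' @export
read_site_counts <- function(path, fragmap, bait, bait_id = "bait",
                             condition = "0h") {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric", "numeric"))
  key_in <- paste(x$chrom, x$site_pos)
  key_fm <- paste(fragmap$sites$chrom, fragmap$sites$pos)
  idx <- match(key_fm, key_in)
  if (anyNA(idx))
    stop("count file is missing ", sum(is.na(idx)),
         " site(s) of the fragment map (first: ",
         key_fm[which(is.na(idx))[1L]], ")")
  site_profile(fragmap, x$count[idx], bait, bait_id, condition)
}

#' Write a track as bedGraph
#' @param df data.frame with `chrom`, `start`, `end` and one value column.
#' @param path Output path.
#' @param value Name of the value column (default the fourth column).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path, value = names(df)[4L]) {
  utils::write.table(
    data.frame(df$chrom, df$start, df$end, df[[value]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph
#' @param path bedGraph file (4 columns, no header).
#' @param value Name to give the value column.
#' @return data.frame `chrom`, `start`, `end`, `<value>`.
#' @export
read_bedgraph <- function(path, value = "value") {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", value),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  x
}

#' Read binned ChIP IP and input bedGraphs into one track
#' @param ip_path,input_path bedGraph files on the same bin grid.
#' @param timepoint Timepoint label.
#' @return A `BinnedChipTrack` data.frame.
#' @export
read_chip_track <- function(ip_path, input_path, timepoint = "0h") {
  ip <- read_bedgraph(ip_path, "ip")
  inp <- read_bedgraph(input_path, "input")
  if (!identical(ip[c("chrom", "start", "end")],
                 inp[c("chrom", "start", "end")]))
    stop("IP and input bedGraphs are not on the same bin grid")
  tr <- cbind(ip, input = inp$input)
  structure(tr, timepoint = timepoint, ip_library_size = sum(tr$ip),
            input_library_size = sum(tr$input),
            class = c("BinnedChipTrack", "data.frame"))
}

#' Write a contact-domain set as BED6
#'
#' Name encodes `bait:condition:scope`; score is the mean p-score times
#' ten, rounded, capped at 1000 as BED requires.
#'
#' @param domains A [call_domains()] set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path) {
  name <- paste(attr(domains, "bait_id") %||% "bait",
                attr(domains, "condition") %||% "NA",
                domains$scope, sep = ":")
  utils::write.table(
    data.frame(domains$chrom, domains$start, domains$end,
               if (nrow(domains)) name else character(0),
               pmin(round(domains$mean_p_score * 10), 1000),
               rep(".", nrow(domains))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of domains or genes
#' @param path BED3+ file.
#' @return data.frame `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score",
                "strand")[seq_len(ncol(x))]
  x
}

#' Write a gene table as TSV
#' @param genes Gene data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene table TSV
#' @param path TSV with header, at least `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (optionally `cluster`).
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!is.null(g$cluster)) g$cluster <- as.character(g$cluster)
  g
}

#' Write an expression table (counts + sample sheet)
#' @param table An [expression_table()].
#' @param counts_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_table <- function(table, counts_path, samples_path) {
  utils::write.table(data.frame(gene_id = rownames(table$counts),
                                table$counts, check.names = FALSE),
                     counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$samples, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read an expression table (counts + sample sheet)
#' @param counts_path TSV, first column `gene_id`, then one column per
#'   sample.
#' @param samples_path TSV with `sample`, `condition`, `replicate`.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(counts_path, samples_path) {
  cnt <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt[[1L]]
  smp <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  smp$condition <- as.character(smp$condition)
  expression_table(m, smp)
}

#' Write a JSON sidecar describing an artifact
#'
#' Every pipeline output gets a sidecar with the parameters that produced
#' it and the md5 checksums of its inputs, so a run is reproducible from
#' its manifests alone.
#'
#' @param artifact_path Path of the artifact the sidecar describes.
#' @param params Named list of parameters.
#' @param inputs Character vector of input file paths to checksum.
#' @return Sidecar path, invisibly.
#' @export
write_sidecar <- function(artifact_path, params = list(),
                          inputs = character(0)) {
  side <- paste0(artifact_path, ".json")
  jsonlite::write_json(
    list(artifact = basename(artifact_path),
         md5 = unname(tools::md5sum(artifact_path)),
         params = params,
         inputs = as.list(stats::setNames(
           unname(tools::md5sum(inputs)), basename(inputs)))),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}
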