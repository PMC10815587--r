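#' Restriction-fragment coordinate grid
#'
#' A `FragmentMap` holds, per chromosome, the ordered HindIII-delimited
#' fragments and the ordered cut-site positions.  It is the coordinate grid
#' on which every per-site 4C statistic in this package is computed.
#'
#' All coordinates are 0-based half-open: a fragment `[start, end)` covers
#' bases `start .. end-1`; a cut site at position `p` is the start
#' coordinate of a motif occurrence.  Within a chromosome fragments tile
#' the sequence exactly (`end[k] == start[k+1]`), so each chromosome has
#' one more fragment than it has sites.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), sorted by chromosome then start, tiling each
#'   chromosome from 0 to its length.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @return An object of class `FragmentMap` with components `fragments`
#'   (data.frame `chrom`,`start`,`end`), `sites` (data.frame `chrom`,`pos`,
#'   one row per interior fragment boundary, in grid order) and
#'   `chrom_lengths`.
#' @export
fragment_map <- function(fragments, chrom_lengths) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.numeric(fragments$start)
  fragments$end   <- as.numeric(fragments$end)
  chroms <- names(chrom_lengths)
  if (is.null(chroms) || anyNA(chroms))
    stop("chrom_lengths must be a named vector")
  sites <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    cc <- chroms[i]
    fr <- fragments[fragments$chrom == cc, , drop = FALSE]
    if (nrow(fr) == 0L)
      stop("no fragments for chromosome ", cc)
    if (is.unsorted(fr$start, strictly = TRUE))
      stop("fragments not sorted on ", cc)
    if (fr$start[1L] != 0)
      stop("first fragment on ", cc, " does not start at 0")
    if (fr$end[nrow(fr)] != chrom_lengths[[cc]])
      stop("last fragment on ", cc, " does not end at chromosome length")
    if (nrow(fr) > 1L) {
      bad <- which(fr$end[-nrow(fr)] != fr$start[-1L])
      if (length(bad))
        stop("fragments ", bad[1L], " and ", bad[1L] + 1L, " on ", cc,
             " do not abut (gap or overlap)")
    }
    if (any(fr$end <= fr$start))
      stop("zero- or negative-width fragment on ", cc)
    cuts <- fr$start[-1L]
    sites[[i]] <- data.frame(chrom = rep(cc, length(cuts)), pos = cuts,
                             stringsAsFactors = FALSE)
  }
  structure(
    list(fragments = fragments,
         sites = do.call(rbind, c(sites, list(make.row.names = FALSE))),
         chrom_lengths = chrom_lengths),
    class = "FragmentMap")
}

#' @export
print.FragmentMap <- function(x, ...) {
  cat("FragmentMap:", length(x$chrom_lengths), "chromosome(s),",
      nrow(x$fragments), "fragments,", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Number of cut sites in a fragment map
#' @param fragmap A [fragment_map()].
#' @param chrom Optional chromosome name; default counts all sites.
#' @return Integer site count.
#' @export
n_sites <- function(fragmap, chrom = NULL) {
  if (is.null(chrom)) nrow(fragmap$sites)
  else sum(fragmap$sites$chrom == chrom)
}

#' In-silico restriction digest of a genome
#'
#' Scans each chromosome for occurrences of the restriction motif (HindIII
#' `AAGCTT` by default) on the forward strand and cuts at every motif start.
#' Complete digestion is assumed; occurrences containing `N` are skipped,
#' so masked regions contribute no phantom sites.  Cut positions are
#' reported at the motif start rather than at the enzymatic overhang
#' offset: only relative site spacing matters downstream.
#'
#' @param sequences Named character vector of chromosome sequences
#'   (alphabet `A,C,G,T,N`), or a [Biostrings::DNAStringSet].
#' @param motif Recognition sequence, default `"AAGCTT"` (palindromic, so a
#'   forward-strand scan is exhaustive).
#' @return A [fragment_map()].
#' @examples
#' fm <- digest_genome(c(chrA = "AAAAAAGCTTAAAAAGCTTA"))
#' fm$sites$pos   # 4, 13
#' @export
digest_genome <- function(sequences, motif = "AAGCTT") {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (is.character(sequences)) {
    if (is.null(names(sequences))) stop("sequences must be named")
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (any(Biostrings::width(sequences) == 0L))
    stop("empty sequence: ",
         paste(names(sequences)[Biostrings::width(sequences) == 0L],
               collapse = ", "))
  lens <- stats::setNames(Biostrings::width(sequences), names(sequences))
  frs <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    cc <- names(sequences)[i]
    L <- lens[[cc]]
    if (nchar(motif) > L) {
      cuts <- integer(0)
    } else {
      # fixed = TRUE: N in the subject matches nothing, so motif hits
      # overlapping N runs are skipped automatically
      m <- Biostrings::matchPattern(motif, sequences[[i]], fixed = TRUE)
      cuts <- BiocGenerics::start(m) - 1L     # to 0-based
    }
    bounds <- unique(c(0, cuts, L))   # a motif at position 0 cuts nothing off
    frs[[i]] <- data.frame(chrom = cc,
                           start = bounds[-length(bounds)],
                           end = bounds[-1L],
                           stringsAsFactors = FALSE)
  }
  fragment_map(do.call(rbind, frs), lens)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that truncates record
#' names at the first whitespace, matching common chromosome naming.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Load a fragment map from a BED3 file
#'
#' The BED must contain 0-based half-open fragment intervals, sorted by
#' (chrom, start), tiling each chromosome exactly.  Violations are reported
#' with the offending line numbers.
#'
#' @param path BED3 file of fragments.
#' @return A [fragment_map()].
#' @export
load_fragment_map <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "numeric", "numeric"))
  if (nrow(bed) == 0L) stop("empty fragment BED: ", path)
  line <- seq_len(nrow(bed))
  # sorted by (chrom, start) with chromosomes in blocks
  chrom_rle <- rle(bed$chrom)
  if (anyDuplicated(chrom_rle$values))
    stop("fragment BED not grouped by chromosome (chromosome ",
         chrom_rle$values[anyDuplicated(chrom_rle$values)],
         " appears in more than one block)")
  for (cc in chrom_rle$values) {
    idx <- which(bed$chrom == cc)
    st <- bed$start[idx]
    en <- bed$end[idx]
    if (is.unsorted(st, strictly = TRUE)) {
      j <- which(diff(st) <= 0)[1L]
      stop("fragment BED not sorted: lines ", line[idx][j], " and ",
           line[idx][j + 1L])
    }
    if (length(idx) > 1L) {
      d <- en[-length(en)] - st[-1L]
      j <- which(d != 0)
      if (length(j))
        stop(if (d[j[1L]] < 0) "gap" else "overlap",
             " between fragments at lines ", line[idx][j[1L]], " and ",
             line[idx][j[1L] + 1L])
    }
  }
  lens <- vapply(split(bed$end, bed$chrom), max, 0)[chrom_rle$values]
  fragment_map(bed, lens)
}

#' Write a fragment map as BED3
#' @param fragmap A [fragment_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(fragmap, path) {
  utils::write.table(fragmap$fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write cut sites as a BED of zero-length features
#' @param fragmap A [fragment_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(fragmap, path) {
  s <- fragmap$sites
  utils::write.table(data.frame(s$chrom, s$pos, s$pos), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
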