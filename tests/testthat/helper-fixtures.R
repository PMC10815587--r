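# shared fixtures: tiny fragment maps and flag tracks built in code

# fragment map with explicit site positions per chromosome
make_fragmap <- function(sites_by_chrom, lengths) {
  frs <- lapply(names(lengths), function(cc) {
    bounds <- c(0, sites_by_chrom[[cc]], lengths[[cc]])
    data.frame(chrom = cc, start = bounds[-length(bounds)],
               end = bounds[-1])
  })
  fragment_map(do.call(rbind, frs), unlist(lengths))
}

# 10 sites at 5,15,...,95 on c1 (length 100); window_bp = 20 covers +/-1 site
toy_fragmap <- function() {
  make_fragmap(list(c1 = seq(5, 95, by = 10)), c(c1 = 100))
}

toy_profile <- function(counts = c(0, 0, 0, 9, 9, 9, 0, 0, 0, 0),
                        fm = toy_fragmap()) {
  site_profile(fm, counts, bait = list(chrom = "c1", pos = 0))
}

# minimal score track for exercising call_domains directly
flag_track <- function(flags, spacing = 10, chrom = "t1") {
  structure(
    data.frame(chrom = chrom, pos = seq_along(flags) * spacing,
               p_score = as.numeric(flags), positive = as.logical(flags)),
    scope = "cis", class = c("WindowScoreTrack", "data.frame"))
}

# independent oracle: run-length enumeration by explicit scanning
brute_force_domains <- function(flags, pos, min_run) {
  out <- list()
  i <- 1L
  n <- length(flags)
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run)
        out[[length(out) + 1L]] <- c(start = pos[i], end = pos[j],
                                     n = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0),
                                      n = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

# bait-proximal zone excluded from precision in recovery metrics
bait_exclusion <- function(scenario = synthetic_scenario(),
                           half_width = 1e6) {
  data.frame(chrom = scenario$bait$chrom,
             start = scenario$bait$pos - half_width,
             end = scenario$bait$pos + half_width)
}
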