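#' Synthetic 4C / expression / ChIP scenario
#'
#' A `SyntheticScenario` is the single declarative description of a
#' desk-scale dataset with the statistical structure the pipeline assumes:
#' a bait-anchored 4C profile with power-law distance decay plus planted
#' associating domains, gene placement denser in active compartments,
#' five-condition irradiation expression kinetics in four clusters, and
#' compartment-dependent gamma-H2AX ChIP dynamics.
#'
#' Defaults encode the stated study design: five conditions
#' (0h, 1Gy-6h, 1Gy-24h, 6Gy-6h, 6Gy-24h); four kinetic cluster shapes
#' (1 = down at 6Gy-6h and 6Gy-24h, 2 = down at both 24 h conditions,
#' 3 = up at 6Gy-24h only, 4 = up at both 24 h conditions); ChIP dynamics
#' over (0h, 3h, 24h) that rise then fall in active compartments and rise
#' late in facultative heterochromatin; a 2 x 20 Mb genome at the 4096 bp
#' expected HindIII spacing.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (scenario, seed).
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param mean_fragment_bp Expected HindIII fragment length (4^6 = 4096).
#' @param bait List `chrom`, `pos`.
#' @param planted_cis_domains,planted_trans_domains data.frames with
#'   columns `chrom`, `anchor` (bp center), `n_sites`, `fold`; resolved to
#'   concrete site runs against a fragment map by
#'   [resolve_planted_domains()].  `NULL` plants nothing.
#' @param decay_exponent Power-law exponent of cis contact decay.
#' @param background_rate Expected cis reads per site at the 100 kb
#'   reference distance.
#' @param distance_floor_bp Distance at which the cis decay saturates
#'   (self-ligation plateau near the bait).
#' @param trans_rate Expected reads per trans site.
#' @param nb_dispersion Negative-binomial dispersion of 4C counts.
#' @param genes_per_mb Named vector of TSS densities (genes/Mb) for
#'   `background`, `active`, `facultative_het` regions.
#' @param cluster_props Named list (same region names) of probabilities
#'   over labels `1`,`2`,`3`,`4`,`stable` for gene cluster assignment.
#' @param cluster_profiles 4 x 5 matrix of condition-wise log2 fold
#'   changes, rows = clusters, columns = conditions.
#' @param expression_baseline,expression_dispersion,n_replicates RNA count
#'   model: per-gene baseline mean count, NB dispersion, replicates per
#'   condition.
#' @param chip_bin_bp,chip_input_rate ChIP bin width and expected input
#'   reads per bin.
#' @param chip_dynamics Named list mapping compartment label to a numeric
#'   vector of IP/input multipliers over `chip_timepoints`.
#' @param chip_timepoints Timepoint labels, default `c("0h","3h","24h")`.
#' @param compartments Optional data.frame `chrom`,`start`,`end`,`label`
#'   overriding the default labelling (planted cis domains = `active`,
#'   planted trans domains = `facultative_het`).
#' @return A list of class `SyntheticScenario`.
#' @export
synthetic_scenario <- function(
    seed = 1L,
    n_chroms = 2L,
    chrom_length_bp = 2e7,
    mean_fragment_bp = 4096,
    bait = list(chrom = "chr1", pos = 1e7),
    planted_cis_domains = data.frame(
      chrom = "chr1", anchor = 1e7 + c(-2.2e6, -1.8e6, -1.4e6,
                                       1.4e6, 1.8e6, 2.2e6),
      n_sites = 30L, fold = 5),
    planted_trans_domains = data.frame(
      chrom = "chr2", anchor = c(2e6, 4e6, 6e6, 8e6, 12e6, 14e6,
                                 16e6, 18e6),
      n_sites = 30L, fold = 5),
    decay_exponent = 1,
    background_rate = 20,
    distance_floor_bp = 2e5,
    trans_rate = 1,
    nb_dispersion = 0.1,
    genes_per_mb = c(background = 5, active = 15, facultative_het = 2),
    cluster_props = list(
      background      = c(`1` = 0.10, `2` = 0.10, `3` = 0.05, `4` = 0.05,
                          stable = 0.70),
      active          = c(`1` = 0.05, `2` = 0.05, `3` = 0.20, `4` = 0.30,
                          stable = 0.40),
      facultative_het = c(`1` = 0.30, `2` = 0.30, `3` = 0.02, `4` = 0.03,
                          stable = 0.35)),
    cluster_profiles = rbind(
      `1` = c(0, 0,  0, -2, -2),
      `2` = c(0, 0, -2,  0, -2),
      `3` = c(0, 0,  0,  0,  2),
      `4` = c(0, 0,  2,  0,  2)),
    expression_baseline = 200,
    expression_dispersion = 0.1,
    n_replicates = 3L,
    chip_bin_bp = 1e4,
    chip_input_rate = 50,
    chip_dynamics = list(active = c(1, 2, 0.8),
                         facultative_het = c(1, 0.9, 1.5)),
    chip_timepoints = c("0h", "3h", "24h"),
    compartments = NULL) {
  conditions <- c("0h", "1Gy-6h", "1Gy-24h", "6Gy-6h", "6Gy-24h")
  colnames(cluster_profiles) <- conditions
  sc <- structure(as.list(environment()), class = "SyntheticScenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(sc$n_chroms >= 1, sc$chrom_length_bp > 0,
            sc$mean_fragment_bp > 0)
  if (sc$background_rate <= 0 || sc$trans_rate <= 0 ||
      sc$nb_dispersion < 0)
    stop("rates must be strictly positive, dispersion non-negative")
  for (d in list(sc$planted_cis_domains, sc$planted_trans_domains)) {
    if (!is.null(d) && nrow(d) && any(d$fold <= 0))
      stop("fold enrichments must be strictly positive")
  }
  if (nrow(sc$cluster_profiles) != 4L || ncol(sc$cluster_profiles) != 5L)
    stop("cluster_profiles must be 4 clusters x 5 conditions")
  if (is.null(names(sc$chip_dynamics)) || any(!nzchar(names(sc$chip_dynamics))))
    stop("chip_dynamics must be a named list")
  invisible(sc)
}

scenario_chroms <- function(sc) paste0("chr", seq_len(sc$n_chroms))

#' Simulate a HindIII fragment map for a scenario
#'
#' Site spacings are exponential with mean `mean_fragment_bp`, matching
#' the occurrence statistics of a 6-mer in an i.i.d. genome, so a
#' sequence-free map is statistically interchangeable with
#' [digest_genome()] output.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [fragment_map()].
#' @export
simulate_fragment_map <- function(scenario) {
  set.seed(scenario$seed + 101L)
  frs <- list()
  lens <- stats::setNames(rep(scenario$chrom_length_bp, scenario$n_chroms),
                          scenario_chroms(scenario))
  for (cc in names(lens)) {
    L <- lens[[cc]]
    n_exp <- ceiling(L / scenario$mean_fragment_bp * 1.3) + 50
    cuts <- cumsum(stats::rexp(n_exp, 1 / scenario$mean_fragment_bp))
    cuts <- unique(round(cuts[cuts < L - 1]))
    cuts <- cuts[cuts > 0]
    bounds <- c(0, cuts, L)
    frs[[cc]] <- data.frame(chrom = cc, start = bounds[-length(bounds)],
                            end = bounds[-1], stringsAsFactors = FALSE)
  }
  fragment_map(do.call(rbind, frs), lens)
}

#' Resolve planted domains to concrete site runs
#'
#' Each planted domain (`chrom`, `anchor`, `n_sites`, `fold`) becomes the
#' run of `n_sites` consecutive HindIII sites centered on the site nearest
#' its anchor.  Domains must lie within chromosome bounds, span at least
#' 20 sites, and not overlap.
#'
#' @param planted data.frame `chrom`, `anchor`, `n_sites`, `fold`.
#' @param fragmap A [fragment_map()].
#' @return data.frame `chrom`, `start`, `end` (positions of the first and
#'   last site of the run, half-open downstream), `fold`, `first_idx`,
#'   `last_idx` (row indices into `fragmap$sites`).
#' @export
resolve_planted_domains <- function(planted, fragmap) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), fold = numeric(0),
                      first_idx = integer(0), last_idx = integer(0))
  if (is.null(planted) || nrow(planted) == 0L) return(empty)
  out <- vector("list", nrow(planted))
  for (i in seq_len(nrow(planted))) {
    cc <- planted$chrom[i]
    if (!cc %in% names(fragmap$chrom_lengths))
      stop("planted domain on unknown chromosome ", cc)
    if (planted$anchor[i] < 0 ||
        planted$anchor[i] > fragmap$chrom_lengths[[cc]])
      stop("planted domain anchor outside chromosome bounds: ",
           cc, ":", planted$anchor[i])
    n <- planted$n_sites[i]
    if (n < 20L) stop("planted domains must span >= 20 sites")
    idx <- which(fragmap$sites$chrom == cc)
    if (length(idx) < n) stop("chromosome ", cc, " has fewer than ",
                              n, " sites")
    center <- idx[which.min(abs(fragmap$sites$pos[idx] -
                                  planted$anchor[i]))]
    first <- min(max(center - (n - 1L) %/% 2L, idx[1L]),
                 idx[length(idx)] - n + 1L)
    last <- first + n - 1L
    out[[i]] <- data.frame(chrom = cc,
                           start = fragmap$sites$pos[first],
                           end = fragmap$sites$pos[last],
                           fold = planted$fold[i],
                           first_idx = first, last_idx = last)
  }
  out <- do.call(rbind, out)
  o <- order(out$chrom, out$start)
  ov <- out[o, ]
  same <- ov$chrom[-nrow(ov)] == ov$chrom[-1L]
  if (any(same & ov$start[-1L] <= ov$end[-nrow(ov)]))
    stop("planted domains overlap")
  out
}

#' Compartment labelling of a scenario
#'
#' Unless overridden in the scenario, planted cis domains are labelled
#' `active` and planted trans domains `facultative_het`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param fragmap A [fragment_map()].
#' @return data.frame `chrom`, `start`, `end`, `label`.
#' @export
scenario_compartments <- function(scenario, fragmap) {
  if (!is.null(scenario$compartments)) return(scenario$compartments)
  cis <- resolve_planted_domains(scenario$planted_cis_domains, fragmap)
  trans <- resolve_planted_domains(scenario$planted_trans_domains, fragmap)
  rbind(
    if (nrow(cis)) data.frame(chrom = cis$chrom, start = cis$start,
                              end = cis$end, label = "active"),
    if (nrow(trans)) data.frame(chrom = trans$chrom, start = trans$start,
                                end = trans$end, label = "facultative_het"))
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate per-site 4C read counts
#'
#' Cis counts are negative binomial with mean
#' `background_rate * (max(d, floor)/1e5)^(-decay_exponent)` at distance
#' `d` from the bait, multiplied by the planted fold inside planted cis
#' domains; trans counts have a low uniform mean, multiplied by the
#' planted fold inside planted trans domains.  The two bait-adjacent
#' sites are set to 0 (self-ligation blind spot).  One profile is drawn
#' per condition from a single stream seeded by the scenario, so a fixed
#' scenario gives bit-identical output.
#'
#' @param scenario A [synthetic_scenario()].
#' @param fragmap A [fragment_map()] covering the scenario genome.
#' @param conditions Conditions to simulate (default all five).
#' @return Named list of [site_profile()], one per condition, with the
#'   resolved planted domains attached as attributes `planted_cis` and
#'   `planted_trans`.
#' @export
simulate_4c_counts <- function(scenario, fragmap,
                               conditions = scenario$conditions) {
  bait <- scenario$bait
  if (!bait$chrom %in% names(fragmap$chrom_lengths))
    stop("bait chromosome not in fragment map")
  cis <- resolve_planted_domains(scenario$planted_cis_domains, fragmap)
  trans <- resolve_planted_domains(scenario$planted_trans_domains, fragmap)
  n <- nrow(fragmap$sites)
  is_cis <- fragmap$sites$chrom == bait$chrom
  d <- abs(fragmap$sites$pos - bait$pos)
  mu <- ifelse(is_cis,
               scenario$background_rate *
                 (pmax(d, scenario$distance_floor_bp) / 1e5) ^
                 (-scenario$decay_exponent),
               scenario$trans_rate)
  fold <- rep(1, n)
  for (dm in list(cis, trans)) {
    for (i in seq_len(nrow(dm)))
      fold[dm$first_idx[i]:dm$last_idx[i]] <- dm$fold[i]
  }
  mu <- mu * fold
  set.seed(scenario$seed)
  out <- lapply(conditions, function(cond) {
    cnt <- nb_draw(n, mu, scenario$nb_dispersion)
    pr <- site_profile(fragmap, cnt, bait, bait_id = "bait1",
                       condition = cond)
    cnt[bait_adjacent_sites(pr, bait, 1L)] <- 0
    site_profile(fragmap, cnt, bait, bait_id = "bait1", condition = cond)
  })
  names(out) <- conditions
  attr(out, "planted_cis") <- cis
  attr(out, "planted_trans") <- trans
  out
}

interval_complement <- function(intervals, L) {
  # intervals: data.frame start,end (sorted, disjoint) on one chromosome
  if (nrow(intervals) == 0L) return(data.frame(start = 0, end = L))
  o <- order(intervals$start)
  st <- intervals$start[o]; en <- intervals$end[o]
  gaps <- data.frame(start = c(0, en), end = c(st, L))
  gaps[gaps$end > gaps$start, , drop = FALSE]
}

#' Simulate a gene annotation table
#'
#' Gene TSSs follow an inhomogeneous Poisson process whose rate depends on
#' the compartment label of the region (genes/Mb from
#' `scenario$genes_per_mb`).  Each gene gets a fixed 10 kb body, a random
#' strand, and an expression-cluster label (1-4 or `stable`) drawn from
#' the region's `cluster_props`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param fragmap A [fragment_map()] (supplies chromosome lengths).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cluster`, `region` (TSS = `start` on `+`, `end - 1` on `-`).
#' @export
simulate_genes <- function(scenario, fragmap) {
  if (any(scenario$genes_per_mb < 0)) stop("gene densities must be >= 0")
  comp <- scenario_compartments(scenario, fragmap)
  set.seed(scenario$seed + 202L)
  body_bp <- 1e4
  rows <- list()
  for (cc in names(fragmap$chrom_lengths)) {
    L <- fragmap$chrom_lengths[[cc]]
    labelled <- comp[comp$chrom == cc, , drop = FALSE]
    regions <- rbind(
      if (nrow(labelled)) data.frame(start = labelled$start,
                                     end = labelled$end,
                                     label = labelled$label),
      cbind(interval_complement(labelled, L), label = "background"))
    for (i in seq_len(nrow(regions))) {
      lab <- regions$label[i]
      rate <- scenario$genes_per_mb[[lab]]
      if (is.null(rate)) stop("no gene density for region label ", lab)
      len <- regions$end[i] - regions$start[i]
      k <- stats::rpois(1, rate * len / 1e6)
      if (k == 0) next
      tss <- sort(round(stats::runif(k, regions$start[i],
                                     regions$end[i] - 1)))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      cl <- sample(names(scenario$cluster_props[[lab]]), k, replace = TRUE,
                   prob = scenario$cluster_props[[lab]])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cc,
        start = ifelse(strand == "+", tss, pmax(tss + 1 - body_bp, 0)),
        end = ifelse(strand == "+", pmin(tss + body_bp, L), tss + 1),
        strand = strand, cluster = cl, region = lab,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), cluster = character(0),
                      region = character(0)))
  g <- do.call(rbind, rows)
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  g <- cbind(gene_id = sprintf("gene%05d", seq_len(nrow(g))), g)
  rownames(g) <- NULL
  g
}

#' Simulate an irradiation time-course expression matrix
#'
#' Raw counts are negative binomial with mean
#' `baseline_g * 2^(logFC of the gene's cluster in that condition)`;
#' per-gene baselines are log-normal around `expression_baseline`, and
#' `stable` genes are flat.
#'
#' @param scenario A [synthetic_scenario()].
#' @param genes data.frame with `gene_id` and `cluster` columns (from
#'   [simulate_genes()] or built directly).
#' @param dispersion,baseline,n_reps Optional overrides of the scenario's
#'   expression parameters.
#' @return An [expression_table()]; the true cluster labels travel with
#'   the `genes` attribute.
#' @export
simulate_expression <- function(scenario, genes,
                                dispersion = scenario$expression_dispersion,
                                baseline = scenario$expression_baseline,
                                n_reps = scenario$n_replicates) {
  prof <- scenario$cluster_profiles
  if (ncol(prof) != 5L) stop("cluster profiles must cover 5 conditions")
  conds <- scenario$conditions
  ng <- nrow(genes)
  set.seed(scenario$seed + 303L)
  base <- stats::rlnorm(ng, log(baseline), 0.7)
  lfc <- matrix(0, ng, length(conds), dimnames = list(NULL, conds))
  planted <- genes$cluster %in% rownames(prof)
  lfc[planted, ] <- prof[genes$cluster[planted], , drop = FALSE]
  samples <- data.frame(
    sample = paste0(rep(conds, each = n_reps), "_r", seq_len(n_reps)),
    condition = rep(conds, each = n_reps),
    replicate = rep(seq_len(n_reps), length(conds)),
    stringsAsFactors = FALSE)
  counts <- matrix(0, ng, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- base * 2 ^ lfc[, samples$condition[j]]
    counts[, j] <- nb_draw(ng, mu, dispersion)
  }
  expression_table(counts, samples, genes = genes)
}

#' Simulate binned gamma-H2AX ChIP IP/input tracks
#'
#' Input counts are uniform Poisson per bin; IP counts are Poisson with
#' mean `input_rate * multiplier(compartment, timepoint)`.  Default
#' multipliers encode the repair kinetics of the study system: active
#' compartments are elevated at 3 h and depleted at 24 h; facultative
#' heterochromatin stays low at 3 h and rises at 24 h.  Bins are assigned
#' to a compartment by midpoint.
#'
#' @param scenario A [synthetic_scenario()].
#' @param fragmap A [fragment_map()] (supplies chromosome lengths).
#' @return Named list over timepoints of `BinnedChipTrack` data.frames
#'   (`chrom`, `start`, `end`, `ip`, `input`, `label`) with attributes
#'   `timepoint`, `ip_library_size`, `input_library_size`.
#' @export
simulate_chip <- function(scenario, fragmap) {
  comp <- scenario_compartments(scenario, fragmap)
  bad <- setdiff(unique(comp$label), names(scenario$chip_dynamics))
  if (length(bad))
    stop("unknown compartment label(s) in chip_dynamics: ",
         paste(bad, collapse = ", "))
  bins <- list()
  for (cc in names(fragmap$chrom_lengths)) {
    L <- fragmap$chrom_lengths[[cc]]
    st <- seq(0, L - 1, by = scenario$chip_bin_bp)
    bins[[cc]] <- data.frame(chrom = cc, start = st,
                             end = pmin(st + scenario$chip_bin_bp, L))
  }
  bins <- do.call(rbind, c(bins, list(make.row.names = FALSE)))
  mid <- (bins$start + bins$end) / 2
  bins$label <- NA_character_
  for (i in seq_len(nrow(comp))) {
    hit <- bins$chrom == comp$chrom[i] & mid >= comp$start[i] &
      mid < comp$end[i]
    bins$label[hit] <- comp$label[i]
  }
  mult <- matrix(1, nrow(bins), length(scenario$chip_timepoints),
                 dimnames = list(NULL, scenario$chip_timepoints))
  for (lab in names(scenario$chip_dynamics)) {
    v <- scenario$chip_dynamics[[lab]]
    if (length(v) != length(scenario$chip_timepoints))
      stop("chip_dynamics for ", lab, " must have one multiplier per ",
           "timepoint")
    mult[which(bins$label %in% lab), ] <-
      matrix(v, sum(bins$label %in% lab, na.rm = TRUE), length(v),
             byrow = TRUE)
  }
  set.seed(scenario$seed + 404L)
  out <- lapply(scenario$chip_timepoints, function(tp) {
    tr <- bins
    tr$input <- stats::rpois(nrow(bins), scenario$chip_input_rate)
    tr$ip <- stats::rpois(nrow(bins),
                          scenario$chip_input_rate * mult[, tp])
    structure(tr, timepoint = tp, ip_library_size = sum(tr$ip),
              input_library_size = sum(tr$input),
              class = c("BinnedChipTrack", "data.frame"))
  })
  names(out) <- scenario$chip_timepoints
  out
}

#' Strong-signal variant of a scenario
#'
#' A deep, clean 4C profile: twelve 40-site cis domains at fold 8 within
#' 3 Mb of the bait.  In this regime the whole top-10% site budget is
#' occupied by genuine signal, so the percentile cutoff clears the
#' permutation-null score range and the empirical FDR collapses toward
#' zero -- the regime in which percentile-thresholded domains are
#' trustworthy.
#'
#' @param seed Integer seed.
#' @param fold Planted fold enrichment (default 8).
#' @return A `SyntheticScenario`.
#' @export
strong_scenario <- function(seed = 1L, fold = 8) {
  synthetic_scenario(
    seed = seed,
    planted_cis_domains = data.frame(
      chrom = "chr1",
      anchor = 1e7 + c(-1, 1) %o% c(1.2e6, 1.55e6, 1.9e6, 2.25e6,
                                    2.6e6, 2.95e6) |> as.vector(),
      n_sites = 40L, fold = fold))
}

#' Null (no-signal) variant of a scenario
#'
#' Removes every planted effect: flat 4C background (decay exponent 0, no
#' planted domains), zero expression fold changes, unit ChIP multipliers,
#' uniform gene density.  Drives every downstream stage to its null
#' behaviour, which is what the negative-control tests assert.  The
#' compartment intervals of the parent scenario are kept as (now
#' effect-free) labels so compartment-conditional statistics remain
#' computable.
#'
#' @param scenario A [synthetic_scenario()].
#' @param keep_decay Keep the distance decay (default FALSE; the decay is
#'   itself genuine contact signal, so the no-signal null removes it).
#' @return A modified `SyntheticScenario`.
#' @export
null_scenario <- function(scenario = synthetic_scenario(),
                          keep_decay = FALSE) {
  fm <- simulate_fragment_map(scenario)
  scenario$compartments <- scenario_compartments(scenario, fm)
  scenario$planted_cis_domains <- NULL
  scenario$planted_trans_domains <- NULL
  if (!keep_decay) scenario$decay_exponent <- 0
  scenario$cluster_profiles[] <- 0
  scenario$chip_dynamics <- lapply(scenario$chip_dynamics,
                                   function(v) rep(1, length(v)))
  scenario$genes_per_mb[] <- scenario$genes_per_mb[["background"]]
  scenario
}
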