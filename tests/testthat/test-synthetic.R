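test_that("generators are pure functions of (scenario, seed)", {
  sc <- synthetic_scenario(seed = 5)
  fm1 <- simulate_fragment_map(sc)
  fm2 <- simulate_fragment_map(sc)
  expect_identical(fm1, fm2)
  p1 <- simulate_4c_counts(sc, fm1, conditions = "0h")[["0h"]]
  p2 <- simulate_4c_counts(sc, fm1, conditions = "0h")[["0h"]]
  expect_identical(p1$count, p2$count)
  g1 <- simulate_genes(sc, fm1)
  g2 <- simulate_genes(sc, fm1)
  expect_identical(g1, g2)
  genes <- g1[seq_len(min(50, nrow(g1))), ]
  e1 <- simulate_expression(sc, genes)
  e2 <- simulate_expression(sc, genes)
  expect_identical(e1$counts, e2$counts)
  c1 <- simulate_chip(sc, fm1)
  c2 <- simulate_chip(sc, fm1)
  expect_identical(c1[["3h"]]$ip, c2[["3h"]]$ip)
})

test_that("simulated fragment spacing matches the digest statistics", {
  sc <- synthetic_scenario(seed = 2)
  fm <- simulate_fragment_map(sc)
  n_expected <- sum(fm$chrom_lengths) / sc$mean_fragment_bp
  expect_lt(abs(nrow(fm$fragments) - n_expected),
            4 * sqrt(n_expected))
  expect_equal(sum(fm$fragments$end - fm$fragments$start),
               sum(fm$chrom_lengths))
})

test_that("4C counts follow the stated mean structure", {
  # trans scope is distance-free: planted fold recovers directly
  ratios <- sapply(1:8, function(s) {
    sc <- synthetic_scenario(seed = s)
    fm <- simulate_fragment_map(sc)
    prs <- simulate_4c_counts(sc, fm, conditions = "0h")
    prof <- prs[["0h"]]
    td <- attr(prs, "planted_trans")
    idx <- unlist(mapply(seq, td$first_idx, td$last_idx))
    on_t <- which(prof$chrom == "chr2")
    c(mean(prof$count[idx]), mean(prof$count[setdiff(on_t, idx)]))
  })
  fold_hat <- mean(ratios[1, ]) / mean(ratios[2, ])
  expect_gt(fold_hat, 4); expect_lt(fold_hat, 6)
  # null generator: trans background matches trans_rate
  scn <- null_scenario(synthetic_scenario(seed = 3))
  fm <- simulate_fragment_map(scn)
  prof <- simulate_4c_counts(scn, fm, conditions = "0h")[["0h"]]
  tcnt <- prof$count[prof$chrom == "chr2"]
  se <- sqrt(stats::var(tcnt) / length(tcnt))
  expect_lt(abs(mean(tcnt) - scn$trans_rate), 3 * se + 1e-9)
})

test_that("bait-adjacent blind spot and bounds checks", {
  sc <- synthetic_scenario(seed = 1)
  fm <- simulate_fragment_map(sc)
  prof <- simulate_4c_counts(sc, fm, conditions = "0h")[["0h"]]
  on_c <- which(prof$chrom == "chr1")
  below <- max(which(prof$pos[on_c] <= sc$bait$pos))
  expect_equal(prof$count[on_c][below], 0)
  expect_equal(prof$count[on_c][below + 1L], 0)

  bad <- synthetic_scenario(seed = 1)
  bad$planted_cis_domains$anchor[1] <- 9e9
  expect_error(simulate_4c_counts(bad, fm), "outside chromosome bounds")
  small <- synthetic_scenario(seed = 1)
  small$planted_cis_domains$n_sites[1] <- 5L
  expect_error(simulate_4c_counts(small, fm), ">= 20 sites")
  expect_error(synthetic_scenario(background_rate = -1), "positive")
})

test_that("overlapping planted domains are rejected", {
  sc <- synthetic_scenario(seed = 1)
  fm <- simulate_fragment_map(sc)
  sc$planted_cis_domains$anchor <- rep(1.2e7, nrow(sc$planted_cis_domains))
  expect_error(resolve_planted_domains(sc$planted_cis_domains, fm),
               "overlap")
})

test_that("gene placement recovers the planted density ratio", {
  dens <- t(sapply(1:10, function(s) {
    sc <- synthetic_scenario(seed = s)
    fm <- simulate_fragment_map(sc)
    g <- simulate_genes(sc, fm)
    comp <- scenario_compartments(sc, fm)
    act <- comp[comp$label == "active", ]
    act_mb <- sum(act$end - act$start) / 1e6
    tss <- ifelse(g$strand == "-", g$end - 1, g$start)
    n_in <- sum(vapply(seq_len(nrow(act)), function(i)
      sum(g$chrom == act$chrom[i] & tss >= act$start[i] &
            tss < act$end[i]), 0L))
    bg_mb <- sum(fm$chrom_lengths) / 1e6 - act_mb   # het regions are small
    c(inside = n_in / act_mb, outside = (nrow(g) - n_in) / bg_mb)
  }))
  ratio <- mean(dens[, "inside"]) / mean(dens[, "outside"])
  expect_gt(ratio, 2.2); expect_lt(ratio, 3.8)

  # uniform profile -> no density difference beyond sampling error
  densu <- t(sapply(1:10, function(s) {
    sc <- null_scenario(synthetic_scenario(seed = s))
    fm <- simulate_fragment_map(sc)
    g <- simulate_genes(sc, fm)
    comp <- sc$compartments
    act <- comp[comp$label == "active", ]
    act_mb <- sum(act$end - act$start) / 1e6
    tss <- ifelse(g$strand == "-", g$end - 1, g$start)
    n_in <- sum(vapply(seq_len(nrow(act)), function(i)
      sum(g$chrom == act$chrom[i] & tss >= act$start[i] &
            tss < act$end[i]), 0L))
    c(inside = n_in / act_mb,
      outside = (nrow(g) - n_in) / (sum(fm$chrom_lengths) / 1e6 - act_mb))
  }))
  ratio_u <- mean(densu[, "inside"]) / mean(densu[, "outside"])
  expect_gt(ratio_u, 0.85); expect_lt(ratio_u, 1.15)

  # zero density -> empty table with full schema
  sc0 <- synthetic_scenario(seed = 1)
  sc0$genes_per_mb[] <- 0
  fm <- simulate_fragment_map(sc0)
  g0 <- simulate_genes(sc0, fm)
  expect_equal(nrow(g0), 0L)
  expect_true(all(c("gene_id", "chrom", "start", "end", "strand",
                    "cluster") %in% names(g0)))
})

test_that("expression generator encodes the kinetic profiles", {
  sc <- synthetic_scenario(seed = 8)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:500),
                      cluster = rep(c("1", "2", "3", "4", "stable"), 100))
  et <- simulate_expression(sc, genes, dispersion = 0.05)
  # raw counts, not CPM: composition shifts would bias the comparison
  mean_cond <- sapply(sc$conditions, function(cond) {
    s <- et$samples$sample[et$samples$condition == cond]
    log2(rowMeans(et$counts[, s, drop = FALSE]) + 0.5)
  })
  lfc_hat <- mean_cond - mean_cond[, "0h"]
  for (cl in rownames(sc$cluster_profiles)) {
    sel <- genes$cluster == cl
    expect_equal(unname(colMeans(lfc_hat[sel, -1])),
                 unname(sc$cluster_profiles[cl, -1]),
                 tolerance = 0.2)
  }
  # profile-shape validation
  bad <- sc; bad$cluster_profiles <- bad$cluster_profiles[, 1:4]
  expect_error(simulate_expression(bad, genes), "5 conditions")
})

test_that("ChIP generator matches its multipliers and validates labels", {
  sc <- synthetic_scenario(seed = 4)
  fm <- simulate_fragment_map(sc)
  # unit multipliers: ratio within [0.95, 1.05] genome-wide
  scn <- sc
  scn$chip_dynamics <- list(active = c(1, 1, 1),
                            facultative_het = c(1, 1, 1))
  tracks <- simulate_chip(scn, fm)
  for (tp in names(tracks)) {
    r <- sum(tracks[[tp]]$ip) / sum(tracks[[tp]]$input)
    expect_gt(r, 0.95); expect_lt(r, 1.05)
  }
  bad <- sc
  bad$compartments <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                                 label = "mystery")
  expect_error(simulate_chip(bad, fm), "unknown compartment")
})
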