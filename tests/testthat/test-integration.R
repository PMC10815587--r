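test_that("gene_density matches hand arithmetic and identities", {
  # 5 TSS inside a single 1 Mb domain, 100 genes on a 100 Mb genome
  genes <- data.frame(
    chrom = "chr1",
    start = c(seq(2e6, 2.8e6, by = 2e5), seq(5e6, 99e6, by = 1e6)),
    strand = "+")
  genes$end <- genes$start + 1e4
  doms <- data.frame(chrom = "chr1", start = 2e6, end = 3e6)
  d <- gene_density(doms, genes, genome_size_bp = 1e8)
  expect_equal(d$density_in_domains, 5)
  expect_equal(d$density_genome, 1)

  # the whole genome as one domain reproduces the genome-wide density
  whole <- data.frame(chrom = "chr1", start = 0, end = 1e8)
  dw <- gene_density(whole, genes, 1e8)
  expect_equal(dw$density_in_domains, dw$density_genome)

  # zero genes: guarded zeros; empty domains: not applicable
  d0 <- gene_density(doms, genes[0, ], 1e8)
  expect_equal(d0$density_genome, 0)
  expect_message(dn <- gene_density(doms[0, ], genes, 1e8),
                 "not applicable")
  expect_true(is.na(dn$density_in_domains))

  # minus-strand TSS is end - 1
  gneg <- data.frame(chrom = "chr1", start = 2.9e6 + 1 - 1e4,
                     end = 2.9e6 + 1, strand = "-")
  expect_equal(gene_density(doms, gneg, 1e8)$n_in_domains, 1L)
})

test_that("cluster_enrichment: worked example, identity, and edge cases", {
  # universe 1000 genes, 100 in domains; cluster of 10 genes, 2 inside
  genes <- data.frame(
    gene_id = sprintf("g%04d", 1:1000), chrom = "chr1",
    start = seq(0, by = 1e4, length.out = 1000), strand = "+",
    cluster = "stable")
  genes$end <- genes$start + 5e3
  doms <- data.frame(chrom = "chr1", start = 0, end = 100 * 1e4)  # first 100
  genes$cluster[c(1, 2, 501:508)] <- "1"    # 2 of 10 inside
  enr <- cluster_enrichment(list(b1 = doms), genes)
  expect_equal(enr$enrichment["1", "b1"], 2)
  expect_equal(enr$log2["1", "b1"], 1)

  # universe against itself: exactly 1
  genes$cluster <- "1"
  enr1 <- cluster_enrichment(list(b1 = doms), genes)
  expect_equal(enr1$enrichment["1", "b1"], 1)

  # cluster disjoint from the domains: enrichment 0 (depletion)
  genes$cluster <- "stable"; genes$cluster[900:909] <- "2"
  enr0 <- cluster_enrichment(list(b1 = doms), genes,
                             clusters = c("1", "2"))
  expect_equal(enr0$enrichment["2", "b1"], 0)
  expect_true(is.na(enr0$enrichment["1", "b1"]))   # empty cluster

  # no universe gene in domains: cells not applicable
  far <- data.frame(chrom = "chr1", start = 9.995e6, end = 9.999e6)
  enrna <- cluster_enrichment(list(b1 = far), genes)
  expect_true(all(is.na(enrna$enrichment)))
})

test_that("null cluster draws give enrichment near 1", {
  set.seed(77)
  vals <- replicate(20, {
    genes <- data.frame(
      gene_id = sprintf("g%04d", 1:1000), chrom = "chr1",
      start = round(runif(1000, 0, 1e7)), strand = "+",
      cluster = "stable")
    genes$end <- genes$start + 100
    genes$cluster[sample(1000, 500)] <- "1"
    doms <- data.frame(chrom = "chr1", start = c(0, 5e6),
                       end = c(2e6, 7.5e6))
    cluster_enrichment(list(b = doms), genes)$enrichment["1", "b"]
  })
  expect_gt(mean(vals), 0.9); expect_lt(mean(vals), 1.1)
})

test_that("chip_signal_in_domains: exactness, refinement, errors", {
  tr <- structure(
    data.frame(chrom = "c1", start = c(0, 100, 200, 300),
               end = c(100, 200, 300, 400),
               ip = c(10, 30, 7, 9), input = c(10, 10, 7, 9)),
    class = c("BinnedChipTrack", "data.frame"))
  doms <- data.frame(chrom = "c1", start = 0, end = 200)
  r <- chip_signal_in_domains(tr, doms, scale_libsize = FALSE)
  expect_equal(r$ratio, 2)
  expect_equal(r$n_bins, 2L)

  # IP identical to input: ratio exactly 1 for any domain set
  tr1 <- tr; tr1$ip <- tr1$input
  expect_equal(chip_signal_in_domains(tr1, doms,
                                      scale_libsize = FALSE)$ratio, 1)

  # refinement: halved bins aligned to the domain give the same ratio
  tr2 <- structure(
    data.frame(chrom = "c1", start = seq(0, 350, 50),
               end = seq(50, 400, 50),
               ip = rep(c(5, 15, 3.5, 4.5), each = 2),
               input = rep(c(5, 5, 3.5, 4.5), each = 2)),
    class = c("BinnedChipTrack", "data.frame"))
  expect_equal(chip_signal_in_domains(tr2, doms,
                                      scale_libsize = FALSE)$ratio, 2)

  # bins straddling the boundary need >= 50% overlap
  doms2 <- data.frame(chrom = "c1", start = 0, end = 150)
  r2 <- chip_signal_in_domains(tr, doms2, scale_libsize = FALSE)
  expect_equal(r2$n_bins, 2L)    # second bin exactly half-covered counts
  doms3 <- data.frame(chrom = "c1", start = 0, end = 140)
  expect_equal(chip_signal_in_domains(tr, doms3,
                                      scale_libsize = FALSE)$n_bins, 1L)

  zero <- tr; zero$input <- 0
  expect_error(chip_signal_in_domains(zero, doms), "zero input")
  expect_error(chip_signal_in_domains(tr, doms[0, ]), "empty domain")
})

test_that("compartment ChIP dynamics recover the planted ordering", {
  sc <- synthetic_scenario(seed = 19)
  fm <- simulate_fragment_map(sc)
  tracks <- simulate_chip(sc, fm)
  comp <- scenario_compartments(sc, fm)
  tab <- chip_dynamics_table(tracks,
                             split(comp[c("chrom", "start", "end")],
                                   comp$label))
  act <- tab$ratio[tab$domain_set == "active"]
  het <- tab$ratio[tab$domain_set == "facultative_het"]
  expect_true(act[2] > act[1] && act[3] < act[1])  # up at 3h, down at 24h
  expect_true(het[2] < 1.05 && het[3] > het[1])    # low, then late rise
})
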