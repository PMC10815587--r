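# spatialcontact

Contact-domain detection and spatial integration for 4C-seq studies of
the ionizing-radiation (IR) response.

## What this package is for

Irradiated tumour cells (the motivating system is U251 glioblastoma
cells at 1 Gy vs 6 Gy, sampled 6 h and 24 h after exposure) reprogram
their transcription in a dose- and time-dependent way, while DNA repair
activity moves between active (A) and heterochromatic (B) nuclear
compartments. 4C-seq measures the genome-wide contact profile of a
chosen viewpoint (*bait*) on a HindIII restriction-fragment grid;
combining the bait's contact domains with expression kinetics and
γH2AX ChIP signal asks where IR-responsive genes sit in the nucleus and
where repair happens over time.

`spatialcontact` implements that analysis as a tested, reusable R
pipeline:

1. **fragment map** — in-silico HindIII digestion (`AAGCTT`) of a FASTA
   genome, or loading/validating a precomputed fragment BED;
2. **contact domains** — for every HindIII site *i*, the read count of
   all sites in a 100 kb window centred on *i* is summed to `S_i` and
   scored against a uniform read-placement null:

   `p_i = P[ Binom(N, k_i / M) >= S_i ]`,  `p-score_i = -log10 p_i`

   with `N` the total reads and `M` the total sites in scope (cis = bait
   chromosome, trans = all others). Sites above the top-10% (cis) or
   top-5% (trans) score percentile are *positive*; runs of **more than
   15 consecutive positive sites** become contact domains. An empirical
   FDR (count permutation across sites, positives re-counted at the
   observed cutoff) qualifies every domain set, and retrieval is gated
   on it (`detect_domains()`);
3. **expression** — CPM, a moderated log-CPM test per contrast against
   0 h (DE iff FDR < 0.05 and |log2FC| > 0.5), and k-means clustering of
   z-scored condition profiles into the four canonical IR kinetic
   classes (1 = early 6 Gy down, 2 = late down both doses, 3 = late
   6 Gy up, 4 = late up both doses);
4. **integration** — gene density (genes/Mb) inside domain unions vs the
   genome, relative enrichment of each expression cluster in each bait's
   domains (with hypergeometric p), and γH2AX ChIP IP/input ratios over
   domain sets per timepoint;
5. **synthetic data** — a generator for all of the above (bait-anchored
   negative-binomial 4C counts with power-law distance decay and planted
   associating domains, compartment-dependent gene density, planted
   kinetic clusters, compartment-dependent ChIP dynamics), so the whole
   pipeline runs from nothing in seconds.

## Worked example

```r
library(spatialcontact)

sc    <- synthetic_scenario(seed = 1)      # 2 x 20 Mb genome, bait chr1:10 Mb
fm    <- simulate_fragment_map(sc)         # ~9,800 HindIII sites
prof  <- simulate_4c_counts(sc, fm, conditions = "0h")[["0h"]]
doms  <- detect_domains(prof, fm, scope = "cis", top_frac = 0.10,
                        fdr_permutations = 50, seed = 1)
head(as.data.frame(doms))
#>   chrom    start      end n_positive_sites mean_p_score scope
#> 1  chr1  7744653  7842575               31     23.81036   cis
#> 2  chr1  8158242  8286180               27     29.38193   cis
#> 3  chr1  8529695  8659970               34     47.68982   cis
#> 4  chr1  9355191 10491897              295     81.58198   cis
#> 5  chr1 11320045 11489977               37     37.81219   cis
#> 6  chr1 11725265 11880324               34     38.07423   cis
attr(doms, "achieved_fdr")
#> [1] 0.006060606
```

Row 4 is the bait's own neighbourhood (the viewpoint-proximal region is
always in contact); the other rows recover the planted associating
domains at 1.4–2.2 Mb from the bait. The permutation FDR of 0.006 says
the top-10% cutoff sits far above anything a shuffled profile produces.

```r
genes <- simulate_genes(sc, fm)
gene_density(doms, genes, sum(fm$chrom_lengths))[1:2]
#> $density_in_domains   6.25        # genes/Mb inside the domain union
#> $density_genome       5.17        # genome-wide control

et <- simulate_expression(sc, genes)
de <- de_all_contrasts(et)           # each condition vs 0h
length(unique(de$gene_id[de$de]))
#> [1] 75                            # DE in >= 1 contrast, of 207 genes
```

The full pipeline (synthesize → domains → expression → integrate, with
JSON sidecars and an md5 manifest) is one call:

```r
run_pipeline(pipeline_config("out_dir", seed = 1))
```

or from the shell, via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/spatialcontact",
                          package="spatialcontact"))') run --out out_dir --seed 1
```

Subcommands `synth`, `domains`, `expression`, `integrate` expose the
stages individually on files (`--counts`, `--fragments`, `--bait
chr:pos`, ...).

## Vignette

`vignettes/spatialcontact-methods.Rmd` documents the statistical model,
every tunable with its default and rationale, what the synthetic
generator does and does not emulate, and the numerical edge-case
decisions.
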