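# triosv

Trio-based discovery and characterisation of de novo structural variants
(dnSVs) from short-read population SV callsets.

## The problem

De novo structural variants — deletions, duplications and inversions that
arise in a parental germline and appear in an offspring but in neither
parent's somatic genome — are roughly a hundred-fold rarer than de novo
point mutations, and short-read SV calling produces candidate sets that are
overwhelmingly false. Pedigreed livestock populations (large full-sib
families, short generation intervals, routinely sequenced three-generation
pedigrees) are an unusually good setting for finding them: a genotyped
sire–dam–proband trio pins the Mendelian expectation, and sequenced
offspring of the proband let a putative dnSV be validated by observing its
transmission.

`triosv` implements that analysis as a tested pipeline for multi-sample SV
VCFs produced by population SV genotyping (per-sample `GT:GQ:AB:SU:PE:SR`
plus duphold-style depth fold-changes `DHFFC`/`DHBFC`), together with a
synthetic cohort generator that plants de novo, inherited, mosaic and
engineered false-positive SVs with known truth, so that every stage is
testable without access to animal sequence data.

## The method

**Candidate screen.** A site is a dnSV candidate in a trio when the proband
is heterozygous, both parents are homozygous reference, and no unrelated
cohort sample carries the allele (sequenced third-generation offspring of
the proband are exempt — a real dnSV is transmitted to about half of them).
Candidates must further satisfy, with all inequalities strict:

| filter | DEL | DUP | INV |
|---|---|---|---|
| trio GQ sum | > 120 | > 120 | > 120 |
| cohort allele frequency | ≤ 0.1 | ≤ 0.1 | ≤ 0.1 |
| proband depth fold-change | DHFFC < 0.8 | DHBFC > 1.1 | — |
| parental mean fold-change | DHFFC > 0.8 | DHBFC < 1.2 | — |
| proband allelic balance | > 0.05 | > 0.1 | > 0.2 |
| proband supporting reads | ≥ 3 | ≥ 3 | ≥ 5 |
| each parent AB / reads | < 0.1, ≤ 3 | < 0.1, ≤ 3 | < 0.1, ≤ 3 |
| site unique to one proband | yes | yes | yes |

**Evidence review.** Five rules proxy manual breakpoint inspection: both
breakpoints in repeats; one-sided support; fewer than three supporting
reads at either breakpoint; mutually disjoint supporting reads; no coverage
shift at the breakpoints (DEL/DUP).

**Characterisation.** Parent of origin from informative SNPs inside the SV
(deletions: the parent homozygous for the allele missing from the proband's
reads; duplications: the parental source of the over-represented allele of
a 2:1 read ratio). Breakpoint homology `h` = longest exact match between
the flanks ending at the two breakpoints: `h ≤ 1` → NON-HOM (e.g.
non-homologous end joining), `2 ≤ h ≤ 15` → MICRO-HOM (e.g.
micro-homology-mediated break-induced replication). Nearby de novo
mutations of one proband cluster into single mutation events
(single-linkage, 50 kb window). A pooled het-SNP minor/major read ratio `r`
inside a deletion gives the deleted-DNA fraction `d = (1 − r)/2`; `d`
far below 0.5 flags mosaicism. The per-generation rate is `k/n` over `n`
trios with a Wilson score interval.

## Worked example

The package ships a catalogue of published dnSV coordinates from a
37-trio pig cohort (`inst/extdata/dnsv_catalogue.tsv`). Clustering the
germline records and estimating the rate:

```r
library(triosv)
tab <- read.delim(system.file("extdata", "dnsv_catalogue.tsv", package = "triosv"))
germ <- tab[tab$event != "mosaic1", ]
cl <- cluster_dnms(data.frame(id = seq_len(nrow(germ)), chrom = germ$chrom,
                              start = germ$start, end = germ$end), 50000)
cl$clusters
#>   cluster_id chrom n  span size_sum
#> 1          1  chr1 3   197      199
#> 2          2  chr1 4 24740    25196
#> 3          3  chr7 1   573      573
#> 4          4 chr15 1    64       64
estimate_rate(nrow(cl$clusters), 37)
#> dnSV rate: 4 / 37 = 0.108 per generation (95% Wilson CI 0.043-0.247)
```

Ten records collapse into four de novo events: a compact 197 bp cluster
(duplication + dnSNV + deletion), a complex 25 kb cluster whose component
sizes sum to 25,196 bp, and two single dnSVs of 573 and 64 bp — a rate of
one dnSV per nine offspring. A pooled 2:1 het-SNP ratio inside a deletion
(`mosaic_fraction(20, 10)`) yields `d = 0.25`, i.e. ~25% of DNA deleted:
a mosaic, excluded from the rate.

The full pipeline on a synthetic study cohort (40 trios at 30×, with 10
planted dnSVs, 200 inherited SVs and 50 engineered false positives):

```r
sim <- simulate_cohort(sim_config(seed = 1))
res <- run_pipeline(sim$cohort, sim$pedigree,
                    bp_evidence = sim$bp_evidence, repeats = sim$repeats,
                    profiles = sim$profiles, snvs = sim$snvs,
                    reference = sim$reference, genes = sim$genes)
res
#> dnSV pipeline result
#>   sites analysed:      262
#>   cascade candidates: 46 (of 76 trio-local)
#>   confirmed dnSVs:     10
#>   de novo events:      10
#> dnSV rate: 10 / 40 = 0.250 per generation (95% Wilson CI 0.142-0.402)
#>   spurious candidates: 78.3%
```

All ten planted dnSVs are confirmed, every inherited SV and false positive
is rejected, and `res$confirmed` carries per-variant parent of origin,
breakpoint homology class, genic context and transmission status.

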