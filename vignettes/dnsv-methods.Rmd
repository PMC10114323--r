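---
title: "Detecting de novo structural variants in trios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting de novo structural variants in trios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triosv)
```

## Scope and data model

`triosv` screens a multi-sample structural-variant callset for de novo
structural variants (dnSVs) in sire–dam–proband trios and characterises
the survivors. The expected input is the output of population SV
genotyping: one VCF site per SV with `SVTYPE`/`END` INFO keys and
per-sample `GT:GQ:AB:SU:PE:SR:DHFFC:DHBFC` evidence, plus a 6-column PED
file. Internally coordinates are 1-based with the VCF `POS` as the base
immediately before the event, so every event size obeys
`length = end - start`; a deletion removes bases `start+1 .. end`. This
convention is deliberate — it reproduces printed catalogue sizes exactly
(e.g. 2,940,384 − 2,940,197 = 187) — but note it differs by one from
fully-closed interval arithmetic, and the anchoring of `POS` (base before
the event versus first affected base) cannot be recovered from sizes
alone. Breakend (`BND`) records are retained on load but flagged excluded:
the class mixes unresolvable signal types and is not analysed.

Missing FORMAT keys become missing evidence and *fail* any filter that
needs them; passing silently on absent evidence would defeat the purpose
of a conservative screen. Only diploid genotypes are interpreted; anything
else is `missing`. Multi-allelic sites are split into one record per ALT.

## The candidate cascade

A trio-local candidate has a heterozygous proband and both parents
homozygous reference (a missing parental genotype disqualifies). On top of
that:

* **Cohort screen.** No unrelated sample may carry the allele. Missing
  genotypes in unrelated samples count as non-carriers — missingness is
  common at SV sites and the allele-frequency filter backstops the rare
  hidden carrier. Sequenced third-generation offspring of the proband are
  *exempt*: a genuine germline dnSV is expected in about half of them, and
  the allele-frequency threshold below is set with exactly this
  transmission headroom in mind.
* **Trio genotype quality.** `GQ(sire) + GQ(dam) + GQ(proband) > 120`,
  strictly.
* **Allele frequency.** `AF = alt alleles / (2 × non-missing genotypes)`
  over the whole cohort; candidates with `AF > 0.1` are excluded (a dnSV
  is a one-time event), `AF = 0.1` exactly is retained.
* **Per-type evidence.** Deletions: proband `DHFFC < 0.8`, parental mean
  `DHFFC > 0.8`, proband `AB > 0.05`, ≥ 3 supporting reads. Duplications:
  proband `DHBFC > 1.1`, parental mean `DHBFC < 1.2`, `AB > 0.1`, ≥ 3
  reads. Inversions carry no copy-number signal, so only `AB > 0.2` and
  ≥ 5 reads. In all types each parent individually needs `AB < 0.1` and
  at most 3 supporting reads — "either parent" is read as a per-parent
  bound, not a bound on the pair.
* **Uniqueness.** A site that is a trio-local de novo candidate in more
  than one proband is removed everywhere: identical "de novo" calls in
  several unrelated probands are systematic artefacts (in practice,
  repeat-driven inversion calls). Recurrence is counted over trio-local
  patterns; the cohort screen above already rejects such sites for each
  trio, so in the trace a recurrent site fails both checks.

Every inequality is strict exactly as stated; boundary values behave
accordingly (a GQ sum of 120 fails, a DHBFC of 1.1 fails). All filters are
pure predicates of the cohort, evaluated unconditionally and recorded in a
per-candidate trace, so the surviving set is independent of application
order. `DHFFC` is the median depth inside the SV over the median of the
1,000 bp flanks; `DHBFC` uses the median over genome bins in the same GC
stratum (0.05-wide strata, the behaviour of the depth-annotation tools
this field uses; when a stratum is empty outside the interval the
genome-wide median substitutes, flagged in the result).

## Review rules

Manual breakpoint inspection is encoded as five predicates over
breakpoint-local evidence; a candidate is spurious if any fires:

1. both breakpoints overlap repeat intervals (±50 bp windows; the window
   is a proxy parameter — no printed value exists for "overlapping");
2. only one breakpoint has split-read/discordant-pair support;
3. fewer than 3 supporting reads at either breakpoint;
4. the supporting reads at a breakpoint are pairwise disjoint (no base
   covered twice — mutually non-overlapping "support" is scatter, not a
   junction);
5. no coverage shift at the breakpoints for copy-number types. The shift
   is measured as the interior/exterior median-depth ratio over 500 bp on
   each side of each breakpoint — an orientation-free restatement of
   "depth after versus before" that makes a deletion read ≤ 0.8 at *both*
   breakpoints; thresholds reuse the cascade's fold-change cutoffs (0.8
   and 1.1) as numeric stand-ins for a "clear visual" change. A shift at
   one breakpoint suffices; inversions skip the rule.

Missing evidence for a side counts as absent support (rules 2–3), never as
a pass.

## Characterisation

**Parent of origin.** For a deletion, an informative SNP has the proband
apparently homozygous (minor-read fraction ≤ 0.1) while exactly one parent
is homozygous for the unseen allele; that parent's obligate allele is
missing from the proband's reads, so the deletion lies on that parent's
haplotype. This generalises the textbook case (proband homozygous-ALT,
one parent homozygous-REF) to either allele. For a duplication, an
informative SNP is heterozygous with a pooled minor fraction in
[0.28, 0.40] (expectation 1/3 for a 2:1 ratio); the excess allele sits on
the duplicated haplotype and its parental source, when unambiguous under
Mendelian transmission, names the origin. SNPs vote; non-informative
configurations abstain; any disagreement returns `unknown`.

**Mechanism.** Junction homology is the longest exact match between the
reference flanks ending at the two breakpoints (under the coordinate
convention, deletion and tandem-duplication junctions reduce to the same
suffix comparison; for inversions the reverse complement of the distal
flank is also tried). 0–1 bp → `NON_HOM`, 2–15 bp → `MICRO_HOM`, longer →
`unresolved`, since macro-homology cannot be established reliably from
short reads. The 20 bp default flank caps detectable homology well above
the 15 bp class boundary.

**Clusters.** De novo mutations of one proband within 50 kb (single
linkage) form one mutation event. No printed definition of "cluster"
exists; 50 kb accommodates both observed shapes — a compact ~200 bp
cluster and a complex ~25 kb one — and sits above the < 20 kb window used
for clustered point mutations in the human literature. Both `span`
(`max(end) − min(start)`) and `size_sum` (sum of member lengths) are
reported because complex clusters with overlapping members are quoted by
component sum, compact ones by span. Clustering is restricted to
mutations of the same proband: co-location of events from different
individuals is coincidence, not a mutational event. Point mutations
(dnSNVs) may be supplied as additional cluster members; calling them is
out of scope.

**Mosaicism.** Inside a deletion carried by a fraction `m` of cells, the
allele on the deleted haplotype keeps `1 − m` of its reads, so the pooled
minor/major het-SNP ratio is `r = 1 − m` and the deleted-DNA fraction is
`d = m/2 = (1 − r)/2`: 0.5 for a germline heterozygote (`r = 0`,
hemizygous signal), 0.25 for a 2:1 ratio. Zygosity is `germline` when `d`
is within 0.1 of 0.5. Whether mosaicism is somatic or germline cannot be
resolved from this signal and is not claimed.

**Rate.** `rate = k/n` dnSV events per generation over `n` trios, with
the Wilson score interval (`z = 1.959964` at 95%; the difference from
1.96 is immaterial at these `n` but the exact quantile is used). Mosaic
calls are excluded from `k` and clustered mutations count once. The
Wilson interval was chosen over Wald/exact because it behaves well at
small `k`; `stats::prop.test(correct = FALSE)` serves as an independent
cross-check in the tests. For the worked example `k = 4, n = 37` the
implementation reports the standard Wilson interval (0.043–0.247); a
published interval of (0.038–0.255) for the same counts matches neither
Wilson nor the common alternatives exactly, and no attempt is made to
reverse-engineer that variant.

**Transmission.** A heterozygous dnSV reaches each offspring
independently with probability 1/2, so `n` sequenced offspring catch a
transmission with probability `1 − 2^-n` (93.75% at 4; 99.6–99.9% at
8–10). A dnSV is `validated` when a sequenced offspring is heterozygous
at the site.

## The synthetic cohort

`simulate_cohort()` generates the full input surface with planted truth.
Defaults describe the emulated study conditions: two lines of 20 trios at
a mean depth of 30× (per-sample depths N(30, 2²)), four line-1 probands
reused as sires (providing sequenced third-generation offspring, two
planted dnSVs transmitted), 10 de novo SVs, 200 inherited polymorphisms
(founder frequencies U(0.05, 0.3), genotypes transmitted Mendelianly
through the pedigree), 2 mosaic deletions (m = 0.5) and 50 false
positives cycling through seven failure modes — one per filter or review
rule they must trip. SV sizes are log-uniform on 150–5,000 bp over a
6 × 400 kb i.i.d. random reference; breakpoint homology of 0–15 bp
(weighted toward 0–1 bp, the mechanism mix reported for real dnSVs) is
planted by editing the reference flanks with a forced mismatch one base
beyond.

Carrier evidence centres: allelic balance `0.5 m` (Beta, concentration
80, the spread of a junction-read tally at 30×), supporting reads
Binomial(depth, m/2), and depth fold-changes `1 − dose/2` (DEL) /
`1 + dose/2` (DUP) with `dose = m/2` for heterozygotes — i.e. 0.75/1.25
for a germline het, s.d. 0.01, the tightness of a median over kilobase
windows at 30×. These centres are design choices of the generator, made
so that clean carriers pass the printed thresholds with margin; no
quantitative evidence distributions for true versus false SV calls are
published to calibrate against. Non-carriers have near-zero AB
(Beta(1, 199)) and Poisson(0.2) spurious supporting reads. Depth profiles
(100 bp bins, Poisson-matched noise) carry the planted coverage steps for
every proband. Note one corollary: a mosaic deletion at m = 0.5 has
DHFFC ≈ 0.875 under this model and is filtered by the cascade rather
than surviving to review — mosaic inference is therefore exercised on the
planted SNP ratios directly.

What the generator does *not* emulate: read-level data (no FASTQ/BAM),
alignment artefacts, GC bias (hooks exist in the profile container),
segmental duplication structure, genotyping error in parents beyond the
engineered failure modes, and real genome repeat content. Passing the
end-to-end recovery tests therefore demonstrates that the implementation
applies the stated rules correctly and recovers planted signal under the
stated noise model — not that the thresholds themselves are optimal for
any particular real dataset.

## Numerical and degenerate-input choices

* Flank and window sizes: DHFFC flanks 1,000 bp; review step windows 500 bp;
  repeat windows ±50 bp; junction flanks 20 bp. All configurable.
* A zero flank median makes DHFFC `+Inf` (never a silent pass of `< 0.8`).
* Zero genotyped samples at a site is an error for AF, not an NA.
* `mosaic_fraction` with zero reads overall returns the hemizygous
  interpretation (`d = 0.5`, germline).
* Problem sizes in the test-suite: the synthetic acceptance cohort is
  262 sites × 116 samples; calibration checks use ~600 inherited sites;
  the Wilson coverage check uses 10,000 binomial draws; the
  parent-of-origin studies use 100 SVs × 6 SNPs. These sizes give
  sub-minute runtimes while keeping Monte-Carlo standard errors well
  inside the asserted tolerances.
* Seeds fix generator output byte-for-byte; the generator seeds the
  global RNG (documented, standard for simulation code in this field).

## Known limitations

Only deletions, duplications and inversions are analysed; translocations
and insertions land in the breakend class and are dropped. The review
rules are numeric proxies for visual inspection and inherit its
subjectivity through their window/threshold choices. Parent-of-origin
assignment needs informative SNPs inside the SV, so small dnSVs usually
return `unknown`. Homology beyond the junction flank (macro-homology,
e.g. non-allelic homologous recombination) is reported `unresolved`, a
known blind spot of short-read data. The rate estimator treats trios as
exchangeable Bernoulli trials; with a handful of events the interval is
wide and line- or parent-specific rates are not identifiable.
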