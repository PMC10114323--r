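# Characterisation of confirmed dnSVs: parent of origin, breakpoint
# homology and mutation mechanism, clustering, mosaic fraction, genic
# context, transmission, and the per-generation dnSV rate.

#' Assign the parent of origin of a dnSV from informative SNPs
#'
#' Uses SNPs inside the SV breakpoints whose trio genotypes pin the mutant
#' haplotype to one parent.
#'
#' For a de novo **deletion** an informative SNP has the proband apparently
#' homozygous (only one allele in its reads) while exactly one parent is
#' homozygous for the other allele: that parent's obligately transmitted
#' allele is missing from the proband's reads, so the deletion sits on that
#' parent's haplotype.
#'
#' For a de novo **duplication** an informative SNP is heterozygous in the
#' proband with an approximate 2:1 read ratio; the over-represented allele
#' lies on the duplicated haplotype, and when its parental source is
#' unambiguous (e.g. one parent homozygous for the minor allele) that parent
#' is the origin.
#'
#' SNPs vote individually; SNPs that do not match the informative
#' configuration abstain.  All votes must agree; conflicting votes return
#' `"unknown"`, as does the absence of any informative SNP.
#'
#' @param sv list or one-row data.frame with `chrom`, `start`, `end`,
#'   `svtype` (`DEL` or `DUP`).
#' @param snvs data.frame of small variants with columns `chrom`, `pos`,
#'   `sample`, `gt`, `ref_reads`, `alt_reads` (one row per sample at each
#'   site), covering at least the three trio members.
#' @param trio list or one-row data.frame with `sire`, `dam`, `proband`.
#' @param dup_minor_band inclusive range of the pooled minor-read fraction
#'   accepted as a 2:1 ratio (default `c(0.28, 0.40)`, expectation 1/3).
#' @param hom_max_minor maximum minor-read fraction at which the proband is
#'   treated as apparently homozygous for the deletion rule (default 0.1).
#' @return `"paternal"`, `"maternal"` or `"unknown"`.
#' @export
assign_parent_of_origin <- function(sv, snvs, trio,
                                    dup_minor_band = c(0.28, 0.40),
                                    hom_max_minor = 0.1) {
  if (!sv$svtype %in% c("DEL", "DUP")) return("unknown")
  inside <- snvs$chrom == sv$chrom & snvs$pos > sv$start & snvs$pos <= sv$end
  snvs <- snvs[inside, , drop = FALSE]
  if (!nrow(snvs)) return("unknown")
  votes <- character(0)
  for (p in unique(snvs$pos)) {
    rows <- snvs[snvs$pos == p, ]
    pr <- rows[rows$sample == trio$proband, ]
    si <- rows[rows$sample == trio$sire, ]
    da <- rows[rows$sample == trio$dam, ]
    if (nrow(pr) != 1 || nrow(si) != 1 || nrow(da) != 1) next
    v <- if (sv$svtype == "DEL") {
      poo_vote_del(pr, si, da, hom_max_minor)
    } else {
      poo_vote_dup(pr, si, da, dup_minor_band)
    }
    if (!is.na(v)) votes <- c(votes, v)
  }
  if (!length(votes)) return("unknown")
  if (length(unique(votes)) > 1) return("unknown")
  votes[1]
}

# alleles carried by a genotype code, as c(ref_copies, alt_copies)
gt_alleles <- function(gt) {
  switch(gt, hom_ref = c(2L, 0L), het = c(1L, 1L), hom_alt = c(0L, 2L),
         c(NA_integer_, NA_integer_))
}

poo_vote_del <- function(pr, si, da, hom_max_minor) {
  tot <- pr$ref_reads + pr$alt_reads
  if (is.na(tot) || tot == 0) return(NA_character_)
  minor <- min(pr$ref_reads, pr$alt_reads) / tot
  if (minor > hom_max_minor) return(NA_character_)
  seen_alt <- pr$alt_reads > pr$ref_reads     # allele visible in reads
  absent <- if (seen_alt) "hom_ref" else "hom_alt"  # parent hom for unseen allele
  hit <- c(sire = identical(si$gt, absent), dam = identical(da$gt, absent))
  if (sum(hit) != 1) return(NA_character_)
  if (hit["sire"]) "paternal" else "maternal"
}

poo_vote_dup <- function(pr, si, da, band) {
  tot <- pr$ref_reads + pr$alt_reads
  if (is.na(tot) || tot == 0 || pr$ref_reads == 0 || pr$alt_reads == 0) {
    return(NA_character_)
  }
  minor <- min(pr$ref_reads, pr$alt_reads) / tot
  if (minor < band[1] || minor > band[2]) return(NA_character_)
  excess_alt <- pr$alt_reads > pr$ref_reads
  # excess allele index: 2 = alt, 1 = ref; other allele is the minor one
  e <- if (excess_alt) 2L else 1L
  o <- 3L - e
  sa <- gt_alleles(si$gt); dalle <- gt_alleles(da$gt)
  if (any(is.na(sa)) || any(is.na(dalle))) return(NA_character_)
  # transmission assignments consistent with proband carrying both alleles:
  # excess from sire requires sire to carry e and dam to carry o, and vice versa
  from_sire <- sa[e] > 0 && dalle[o] > 0
  from_dam <- dalle[e] > 0 && sa[o] > 0
  if (from_sire == from_dam) return(NA_character_)  # ambiguous or impossible
  if (from_sire) "paternal" else "maternal"
}

# ---------------------------------------------------------------------------

# longest common suffix of two equal-orientation character strings
common_suffix_len <- function(a, b) {
  av <- rev(strsplit(a, "")[[1]])
  bv <- rev(strsplit(b, "")[[1]])
  n <- min(length(av), length(bv))
  if (n == 0) return(0L)
  mism <- which(av[1:n] != bv[1:n])
  if (!length(mism)) n else mism[1] - 1L
}

chrom_string <- function(reference, chrom) {
  if (is.character(reference) && is.null(names(reference)) && length(reference) == 1) {
    return(reference)
  }
  if (is.character(reference)) return(reference[[chrom]])
  as.character(reference[[chrom]])  # DNAStringSet / list of DNAString
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Breakpoint homology length of an SV junction
#'
#' The length of the longest exact sequence match between the donor-side
#' flank ending at the first breakpoint and the acceptor-side flank ending
#' at the second breakpoint, i.e. the micro-homology a replication- or
#' end-joining-based mechanism could have used.  Under the coordinate
#' convention used throughout (event occupies `start + 1 .. end`), deletion
#' and tandem-duplication junctions both reduce to the longest common suffix
#' of the reference flanks ending at `start` and at `end`.  For inversions
#' the reverse-complement orientation of the distal flank is also tried and
#' the maximum returned.
#'
#' @param reference named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences (or a single unnamed sequence string).
#' @param sv list or one-row data.frame with `chrom`, `start`, `end`,
#'   `svtype`.
#' @param flank flank length examined on each side (default 20 bp; the
#'   result is capped at `flank`).
#' @param junction optional junction contig spanning the breakpoint; must
#'   provide at least `flank` bases on each side or the call returns `NA`
#'   (unresolved).
#' @return Integer homology length, or `NA` when unresolved.
#' @export
junction_homology <- function(reference, sv, flank = 20L, junction = NULL) {
  if (!is.null(junction) && nchar(junction) < 2 * flank) return(NA_integer_)
  s <- chrom_string(reference, sv$chrom)
  if (sv$start - flank + 1 < 1 || sv$end + flank > nchar(s)) return(NA_integer_)
  f1 <- substr(s, sv$start - flank + 1, sv$start)
  f2 <- substr(s, sv$end - flank + 1, sv$end)
  h <- common_suffix_len(f1, f2)
  if (identical(sv$svtype, "INV")) {
    f2r <- revcomp(substr(s, sv$end + 1, sv$end + flank))
    h <- max(h, common_suffix_len(f1, f2r))
  }
  min(as.integer(h), as.integer(flank))
}

#' Classify the mutation mechanism from breakpoint homology
#'
#' 0--1 bp of homology indicates a non-homology-based mechanism such as
#' non-homologous end joining (`NON_HOM`); 2--15 bp indicates a
#' micro-homology-mediated mechanism such as micro-homology-mediated
#' break-induced replication or end joining (`MICRO_HOM`).  Longer
#' (macro-)homology is hard to establish from short reads and is reported
#' `unresolved`, as is an unknown homology length.
#'
#' @param homology_len integer vector of homology lengths (`NA` allowed).
#' @return Character vector in `{"NON_HOM", "MICRO_HOM", "unresolved"}`.
#' @export
classify_mechanism <- function(homology_len) {
  if (any(!is.na(homology_len) & homology_len < 0)) {
    stop("homology length cannot be negative")
  }
  out <- rep("unresolved", length(homology_len))
  out[!is.na(homology_len) & homology_len <= 1] <- "NON_HOM"
  out[!is.na(homology_len) & homology_len >= 2 & homology_len <= 15] <- "MICRO_HOM"
  out
}

#' Cluster de novo mutations by physical proximity
#'
#' Single-linkage grouping: two mutations join one cluster when their
#' intervals lie within `window_bp` of each other on the same chromosome.
#' Each cluster reports its member count, its genomic `span`
#' (`max(end) - min(start)`) and `size_sum`, the sum of member lengths;
#' complex events built from overlapping members can have `size_sum`
#' exceeding the span.  Point mutations (dnSNVs) may be included as members
#' with `start == end` and length as given (1 for a SNV).
#'
#' @param dnms data.frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `length` (default `end - start`, minimum 1).
#' @param window_bp clustering window (default 50000).
#' @return list with `clusters` (cluster_id, chrom, n, span, size_sum) and
#'   `members` (`dnms` with `cluster_id` appended).
#' @export
cluster_dnms <- function(dnms, window_bp = 50000L) {
  if (!nrow(dnms)) {
    return(list(clusters = data.frame(cluster_id = integer(0), chrom = character(0),
                                      n = integer(0), span = integer(0),
                                      size_sum = numeric(0)),
                members = cbind(dnms, cluster_id = integer(0))))
  }
  if (is.null(dnms$length)) dnms$length <- pmax(dnms$end - dnms$start, 1L)
  gr <- GenomicRanges::GRanges(dnms$chrom,
                               IRanges::IRanges(dnms$start, dnms$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = window_bp + 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  cl <- integer(nrow(dnms))
  cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  dnms$cluster_id <- cl
  agg <- lapply(sort(unique(cl)), function(i) {
    m <- dnms[dnms$cluster_id == i, ]
    data.frame(cluster_id = i, chrom = m$chrom[1], n = nrow(m),
               span = max(m$end) - min(m$start), size_sum = sum(m$length))
  })
  list(clusters = do.call(rbind, agg), members = dnms)
}

#' Mosaic cell fraction from het-SNP read ratios inside a deletion
#'
#' Pools the minor/major read counts of heterozygous SNPs inside a deletion.
#' With a fraction `m` of cells carrying the deletion, the allele on the
#' deleted haplotype retains a fraction `1 - m` of its reads, so the pooled
#' minor/major ratio is `r = 1 - m`; the fraction of DNA deleted at the
#' locus is `d = m/2 = (1 - r)/2` (0.5 for a fully germline heterozygous
#' deletion, 0.25 for a 2:1 ratio).  Zygosity is `germline` when `d` lies
#' within `delta` of 0.5, `mosaic` otherwise.
#'
#' @param ref_reads,alt_reads integer vectors of per-SNP read counts in the
#'   proband.
#' @param delta germline tolerance on `d` (default 0.1).
#' @return list with `r` (pooled minor/major ratio), `m` (cell fraction),
#'   `d` (deleted-DNA fraction) and `zygosity`.
#' @export
mosaic_fraction <- function(ref_reads, alt_reads, delta = 0.1) {
  stopifnot(length(ref_reads) == length(alt_reads), length(ref_reads) >= 1,
            all(ref_reads >= 0), all(alt_reads >= 0))
  minor <- sum(pmin(ref_reads, alt_reads))
  major <- sum(pmax(ref_reads, alt_reads))
  if (major == 0) {  # no reads at all: hemizygous signal
    return(list(r = 0, m = 1, d = 0.5, zygosity = "germline"))
  }
  r <- minor / major
  m <- 1 - r
  d <- m / 2
  list(r = r, m = m, d = d,
       zygosity = if (d >= 0.5 - delta) "germline" else "mosaic")
}

#' Per-generation dnSV rate with a Wilson confidence interval
#'
#' `rate = k / n` de novo SV events per offspring generation, with the
#' Wilson score interval for a binomial proportion:
#' centre `(k + z^2/2) / (n + z^2)`, half-width
#' `z * sqrt(k (n - k)/n + z^2/4) / (n + z^2)`.
#'
#' @param k number of identified true dnSVs (clustered mutations count once).
#' @param n number of trios analysed.
#' @param conf confidence level (default 0.95; `z = qnorm(1 - (1-conf)/2)`,
#'   1.959964 at 95%).
#' @return Object of class `rate_estimate`: `k`, `n`, `rate`, `ci_low`,
#'   `ci_high`, `conf`, `z`, `method`.
#' @export
estimate_rate <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1)
  if (n < 1) stop("rate estimation needs at least one trio")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (k + z^2 / 2) / (n + z^2)
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / (n + z^2)
  structure(list(k = k, n = n, rate = k / n,
                 ci_low = max(0, centre - half), ci_high = centre + half,
                 conf = conf, z = z, method = "wilson"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("dnSV rate: %d / %d = %.3f per generation (%.0f%% Wilson CI %.3f-%.3f)\n",
              x$k, x$n, x$rate, 100 * x$conf, x$ci_low, x$ci_high))
  invisible(x)
}

#' Probability of observing a dnSV in at least one sequenced offspring
#'
#' A heterozygous germline dnSV is transmitted to each offspring
#' independently with probability 1/2, so sequencing `n` third-generation
#' offspring detects the transmission with probability `1 - (1/2)^n`
#' (93.75% at n = 4, 99.6% at 8, 99.9% at 10).
#'
#' @param n_offspring number of sequenced offspring (vectorised).
#' @export
transmission_probability <- function(n_offspring) {
  stopifnot(all(n_offspring >= 0))
  1 - 0.5^n_offspring
}

#' Check transmission of a dnSV in sequenced offspring of the proband
#'
#' @param id site id of the confirmed dnSV.
#' @param proband proband sample id.
#' @param cohort An [sv_cohort()].
#' @param pedigree A [pedigree()].
#' @return `"validated"` when at least one sequenced offspring is
#'   heterozygous at the site, `"no_offspring"` when the proband has no
#'   sequenced offspring, `"not_observed"` otherwise.
#' @export
check_transmission <- function(id, proband, cohort, pedigree) {
  off <- offspring_of(pedigree, proband)
  if (!length(off)) return("no_offspring")
  gt <- evidence_field(cohort, "gt")[id, off]
  if (any(gt == "het")) "validated" else "not_observed"
}

#' Genic context of a dnSV
#'
#' `exonic` when the SV interval intersects any exon; otherwise `intronic`
#' when it lies in a gene body (with the intron ordinal, e.g. `"intron
#' 1/19"`, when the SV falls in a single intron of a single-transcript gene
#' model; ordinals count from the 5' end, so they are reversed on the minus
#' strand); `intergenic` otherwise.
#'
#' @param sv list or one-row data.frame with `chrom`, `start`, `end`.
#' @param genes `GRanges` of `gene` and `exon` features with a `gene_id`
#'   column (see [read_gene_annotation()]).
#' @return list with `context`, `gene_ids` and `intron` (label or `NA`).
#' @export
genic_context <- function(sv, genes) {
  iv <- GenomicRanges::GRanges(sv$chrom,
                               IRanges::IRanges(sv$start + 1L, sv$end))
  ex <- genes[genes$type == "exon"]
  gn <- genes[genes$type == "gene"]
  ex_hit <- GenomicRanges::findOverlaps(iv, ex)
  gn_hit <- GenomicRanges::findOverlaps(iv, gn)
  gids <- unique(gn$gene_id[S4Vectors::subjectHits(gn_hit)])
  if (length(ex_hit)) {
    return(list(context = "exonic",
                gene_ids = unique(c(gids, ex$gene_id[S4Vectors::subjectHits(ex_hit)])),
                intron = NA_character_))
  }
  if (!length(gn_hit)) {
    return(list(context = "intergenic", gene_ids = character(0),
                intron = NA_character_))
  }
  intron <- NA_character_
  if (length(gids) == 1) {
    e <- ex[ex$gene_id == gids]
    e <- e[order(GenomicRanges::start(e))]
    n_intron <- length(e) - 1L
    if (n_intron >= 1) {
      ends <- GenomicRanges::end(e)[-length(e)]
      starts <- GenomicRanges::start(e)[-1]
      i <- which(sv$start + 1L > ends & sv$end < starts)
      if (length(i) == 1) {
        g <- gn[gn$gene_id == gids]
        if (as.character(GenomicRanges::strand(g))[1] == "-") {
          i <- n_intron - i + 1L
        }
        intron <- sprintf("intron %d/%d", i, n_intron)
      }
    }
  }
  list(context = "intronic", gene_ids = gids, intron = intron)
}

#' Proportion of candidate dnSVs rejected as spurious
#'
#' @param n_candidates candidates entering review.
#' @param n_confirmed high-evidence dnSVs confirmed.
#' @return Percentage of spurious candidates (1 d.p. worth of precision is
#'   meaningful at typical cohort sizes).
#' @export
spurious_rate <- function(n_candidates, n_confirmed) {
  stopifnot(n_candidates >= n_confirmed, n_candidates >= 0)
  if (n_candidates == 0) return(0)
  100 * (n_candidates - n_confirmed) / n_candidates
}
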