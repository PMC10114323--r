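trio1 <- list(sire = "S1", dam = "D1", proband = "P1")

snp_row <- function(pos, sample, gt, ref_reads, alt_reads, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T", sample = sample,
             gt = gt, ref_reads = ref_reads, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}

test_that("deletion parent of origin: the parent homozygous for the unseen allele", {
  sv <- list(chrom = "chr1", start = 1000, end = 3000, svtype = "DEL")
  # proband reads show only REF; sire is hom ALT -> sire's allele is deleted
  snvs <- rbind(snp_row(1500, "P1", "hom_ref", 28, 0),
                snp_row(1500, "S1", "hom_alt", 0, 30),
                snp_row(1500, "D1", "hom_ref", 31, 0))
  expect_equal(assign_parent_of_origin(sv, snvs, trio1), "paternal")
  # mirrored: dam hom for the unseen allele
  snvs2 <- rbind(snp_row(1500, "P1", "hom_alt", 0, 28),
                 snp_row(1500, "S1", "hom_alt", 0, 30),
                 snp_row(1500, "D1", "hom_ref", 31, 0))
  expect_equal(assign_parent_of_origin(sv, snvs2, trio1), "maternal")
  # no SNPs inside the breakpoints -> unknown
  outside <- rbind(snp_row(500, "P1", "hom_ref", 28, 0),
                   snp_row(500, "S1", "hom_alt", 0, 30),
                   snp_row(500, "D1", "hom_ref", 31, 0))
  expect_equal(assign_parent_of_origin(sv, outside, trio1), "unknown")
  # both parents homozygous for the same unseen allele -> uninformative
  amb <- rbind(snp_row(1500, "P1", "hom_ref", 28, 0),
               snp_row(1500, "S1", "hom_alt", 0, 30),
               snp_row(1500, "D1", "hom_alt", 0, 29))
  expect_equal(assign_parent_of_origin(sv, amb, trio1), "unknown")
})

test_that("duplication parent of origin follows the excess allele of the 2:1 ratio", {
  sv <- list(chrom = "chr1", start = 1000, end = 3000, svtype = "DUP")
  # proband 2:1 with excess ALT; dam hom_ref so ALT must come from the sire
  snvs <- rbind(snp_row(1500, "P1", "het", 15, 30),
                snp_row(1500, "S1", "het", 14, 16),
                snp_row(1500, "D1", "hom_ref", 30, 0))
  expect_equal(assign_parent_of_origin(sv, snvs, trio1), "paternal")
  # excess REF with sire hom_alt: REF hails from the dam
  snvs2 <- rbind(snp_row(1500, "P1", "het", 30, 15),
                 snp_row(1500, "S1", "hom_alt", 0, 30),
                 snp_row(1500, "D1", "het", 16, 14))
  expect_equal(assign_parent_of_origin(sv, snvs2, trio1), "maternal")
  # balanced reads (no 2:1) abstain -> unknown
  bal <- rbind(snp_row(1500, "P1", "het", 22, 23),
               snp_row(1500, "S1", "het", 14, 16),
               snp_row(1500, "D1", "hom_ref", 30, 0))
  expect_equal(assign_parent_of_origin(sv, bal, trio1), "unknown")
  # conflicting SNP votes (one paternal, one maternal) -> unknown
  conflict <- rbind(snvs,
                    snp_row(2500, "P1", "het", 30, 15),
                    snp_row(2500, "S1", "het", 16, 14),
                    snp_row(2500, "D1", "hom_ref", 30, 0))
  expect_equal(assign_parent_of_origin(sv, conflict, trio1), "unknown")
})

test_that("junction homology recovers planted lengths and inverted-orientation homology", {
  ref <- random_reference(3000, seed = 4)
  sv <- list(chrom = "chr1", start = 1000, end = 2000, svtype = "DEL")
  for (k in c(0, 4, 5, 15)) {
    pl <- plant_junction(ref, sv, k)
    expect_equal(junction_homology(pl$reference, sv), k)
  }
  # a tandem duplication junction shares the same flank arithmetic
  svd <- list(chrom = "chr1", start = 1200, end = 2400, svtype = "DUP")
  pl <- plant_junction(ref, svd, 7)
  expect_equal(junction_homology(pl$reference, svd), 7)
  # inversion: homology planted in reverse-complement orientation
  x <- strsplit(unname(ref), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  svi <- list(chrom = "chr1", start = 1000, end = 2000, svtype = "INV")
  for (j in 1:5) x[1000 - 5 + j] <- comp[[x[2000 + 6 - j]]]
  x[1000 - 5] <- comp[[x[2000 + 6]]]  # forced continuation break
  if (x[1000 - 5] == comp[[x[2000 + 6]]]) x[1000 - 5] <- setdiff(c("A","C","G","T"), comp[[x[2000 + 6]]])[1]
  refi <- setNames(paste(x, collapse = ""), "chr1")
  hi <- junction_homology(refi, svi)
  expect_gte(hi, 5)
  # a junction contig shorter than both flanks is unresolved
  expect_true(is.na(junction_homology(ref, sv, junction = "ACGTACGT")))
  # planting rejects homology longer than the flank
  expect_error(plant_junction(ref, sv, 25), "flank")
})

test_that("mechanism classes partition homology lengths at the printed boundaries", {
  expect_equal(classify_mechanism(c(0, 1, 2, 4, 15, 16, NA)),
               c("NON_HOM", "NON_HOM", "MICRO_HOM", "MICRO_HOM", "MICRO_HOM",
                 "unresolved", "unresolved"))
  expect_error(classify_mechanism(-1), "negative")
})

test_that("published-coordinate clustering: span 197 for the compact cluster, 25,196 summed for the complex one", {
  cat_tsv <- system.file("extdata", "dnsv_catalogue.tsv", package = "triosv")
  cat <- read.delim(cat_tsv, stringsAsFactors = FALSE)
  dnms <- data.frame(id = paste0("d", seq_len(nrow(cat))), chrom = cat$chrom,
                     start = cat$start, end = cat$end, stringsAsFactors = FALSE)
  cl <- cluster_dnms(dnms, window_bp = 50000)
  memb <- cl$members
  c1 <- memb$cluster_id[memb$start == 2940197]
  c2 <- memb$cluster_id[memb$start == 95207720]
  expect_equal(cl$clusters$n[cl$clusters$cluster_id == c1], 3)  # dup + dnSNV + del
  expect_equal(cl$clusters$span[cl$clusters$cluster_id == c1], 197)
  expect_equal(cl$clusters$n[cl$clusters$cluster_id == c2], 4)
  expect_equal(cl$clusters$size_sum[cl$clusters$cluster_id == c2], 25196)
  # the two singles and the mosaic each form singleton clusters
  expect_equal(nrow(cl$clusters), 5)
  # input order does not matter
  cl2 <- cluster_dnms(dnms[sample(nrow(dnms)), ], window_bp = 50000)
  expect_equal(sort(cl2$clusters$size_sum), sort(cl$clusters$size_sum))
  # two DNMs on different chromosomes are singleton clusters
  two <- data.frame(id = c("a", "b"), chrom = c("chr1", "chr2"),
                    start = c(100, 100), end = c(600, 600))
  expect_equal(nrow(cluster_dnms(two, 50000)$clusters), 2)
})

test_that("mosaic fraction follows d = (1 - r)/2 and the germline band", {
  m <- mosaic_fraction(20, 10)          # 2:1
  expect_equal(m$d, 0.25)
  expect_equal(m$zygosity, "mosaic")
  g <- mosaic_fraction(30, 0)           # hemizygous 1:0
  expect_equal(g$d, 0.5)
  expect_equal(g$zygosity, "germline")
  b <- mosaic_fraction(15, 15)          # 1:1, no deletion signal
  expect_equal(b$d, 0)
  e <- mosaic_fraction(30, 10)          # 3:1 -> d = 1/3
  expect_equal(e$d, 1 / 3)
  # monotone decreasing in r over pooled SNPs
  ds <- vapply(seq(0, 30, by = 5),
               function(a) mosaic_fraction(30, a)$d, numeric(1))
  expect_true(all(diff(ds) <= 0))
  expect_equal(mosaic_fraction(0, 0)$d, 0.5)
})

test_that("Wilson rate estimate matches an independent score-interval oracle", {
  r <- estimate_rate(4, 37)
  expect_equal(round(r$rate, 3), 0.108)
  oracle <- stats::prop.test(4, 37, correct = FALSE)$conf.int
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(oracle), tolerance = 1e-10)
  for (k in c(0, 1, 5, 12)) {
    for (n in c(12, 37, 80)) {
      got <- estimate_rate(k, n)
      ora <- stats::prop.test(k, n, correct = FALSE)$conf.int
      expect_equal(c(got$ci_low, got$ci_high), as.numeric(ora), tolerance = 1e-10)
      expect_true(got$ci_low <= got$rate && got$rate <= got$ci_high)
    }
  }
  z <- estimate_rate(0, 37)
  expect_equal(z$rate, 0)
  expect_equal(z$ci_low, 0)
  expect_error(estimate_rate(1, 0), "trio")
  expect_error(estimate_rate(5, 4), "k must")
})

test_that("transmission probability and offspring checks", {
  expect_equal(transmission_probability(4), 0.9375)
  expect_equal(transmission_probability(0), 0)
  expect_equal(round(100 * transmission_probability(10), 1), 99.9)

  ped <- make_ped3()
  mk <- function(gt) make_cohort(list(list(id = "v", start = 1000, end = 1500,
                                           svtype = "DEL", gt = gt)),
                                 ped$samples$id)
  expect_equal(check_transmission("v", "P1", mk(c(P1 = "het", P3 = "het")), ped),
               "validated")
  expect_equal(check_transmission("v", "P1", mk(c(P1 = "het")), ped),
               "not_observed")
  expect_equal(check_transmission("v", "P2", mk(c(P2 = "het")), ped),
               "no_offspring")
})

test_that("genic context resolves intron ordinals, exon overlap and intergenic placement", {
  # 20-exon (19-intron) plus-strand gene model
  ex_starts <- 1000 + 0:19 * 2000
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1000, ex_starts), c(1000 + 19 * 2000 + 100, ex_starts + 100)),
    strand = "+",
    type = c("gene", rep("exon", 20)), gene_id = "PDE10A")
  sv_in1 <- list(chrom = "chr1", start = 1200, end = 2800)  # between exon 1 and 2
  g <- genic_context(sv_in1, gr)
  expect_equal(g$context, "intronic")
  expect_equal(g$intron, "intron 1/19")
  expect_equal(g$gene_ids, "PDE10A")
  # same gene on the minus strand: ordinal flips
  gr_m <- gr; GenomicRanges::strand(gr_m) <- "-"
  expect_equal(genic_context(sv_in1, gr_m)$intron, "intron 19/19")
  # overlapping an exon boundary is exonic
  expect_equal(genic_context(list(chrom = "chr1", start = 2950, end = 3200), gr)$context,
               "exonic")
  # outside all genes
  expect_equal(genic_context(list(chrom = "chr1", start = 60000, end = 61000), gr)$context,
               "intergenic")
})

test_that("gene annotation round trips through GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t9000\t.\t+\t.\tID=gene:G1",
    "chr1\tsrc\texon\t1000\t1100\t.\t+\t.\tID=exon:G1.1;Parent=gene:G1",
    "chr1\tsrc\texon\t8900\t9000\t.\t+\t.\tID=exon:G1.2;Parent=gene:G1"), gff)
  gr <- read_gene_annotation(gff)
  expect_equal(sum(gr$type == "exon"), 2)
  g <- genic_context(list(chrom = "chr1", start = 2000, end = 3000), gr)
  expect_equal(g$context, "intronic")
  expect_equal(g$intron, "intron 1/1")
})

test_that("spurious proportion of the candidate set", {
  expect_equal(round(spurious_rate(163, 4), 1), 97.5)
  expect_equal(spurious_rate(10, 10), 0)
  expect_equal(spurious_rate(0, 0), 0)
})
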