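ped3 <- make_ped3()
all_s <- ped3$samples$id

test_that("Mendelian screen: candidate requires het proband, hom_ref parents, no unrelated carrier", {
  mk <- function(gt) make_cohort(list(list(id = "v", start = 1000, end = 1500,
                                           svtype = "DEL", gt = gt)), all_s)
  # clean de novo pattern in trio 1
  m <- mendelian_candidates(mk(c(P1 = "het")), ped3)
  expect_equal(m$id, "v"); expect_equal(m$proband, "P1")
  # proband hom_ref: not a candidate
  expect_equal(nrow(mendelian_candidates(mk(character(0)), ped3)), 0)
  # unrelated sample het: not a candidate
  expect_equal(nrow(mendelian_candidates(mk(c(P1 = "het", S2 = "het")), ped3)), 0)
  # missing parent genotype disqualifies
  expect_equal(nrow(mendelian_candidates(mk(c(P1 = "het", D1 = "missing")), ped3)), 0)
  # missing genotype in an unrelated sample counts as non-carrier
  expect_equal(nrow(mendelian_candidates(mk(c(P1 = "het", S2 = "missing")), ped3)), 1)
  # a carrier third-generation offspring does not disqualify the proband
  m2 <- mendelian_candidates(mk(c(P1 = "het", P3 = "het")), ped3)
  expect_true("P1" %in% m2$proband)
})

test_that("trio GQ sum must strictly exceed the threshold", {
  expect_true(trio_gq_filter(50, 40, 35)$pass)    # 125
  expect_false(trio_gq_filter(40, 40, 40)$pass)   # 120 exactly
  expect_false(trio_gq_filter(NA, 60, 70)$pass)
  set.seed(3)
  g <- matrix(sample(20:60, 600, replace = TRUE), ncol = 3)
  got <- trio_gq_filter(g[, 1], g[, 2], g[, 3])
  expect_equal(got$pass, rowSums(g) > 120)   # brute-force summation oracle
  expect_equal(got$gq_sum, rowSums(g))
})

test_that("cohort AF counts alt alleles over non-missing genotypes; 0.1 is retained", {
  n <- 37 * 3
  samples <- sprintf("X%03d", seq_len(n))
  gt <- setNames(rep("het", 1), samples[5])
  co <- make_cohort(list(list(id = "v", start = 100, end = 200, svtype = "DEL",
                              gt = gt)), samples)
  expect_equal(unname(cohort_af(co)), 1 / (2 * n))

  gt2 <- setNames(c("het", "missing"), samples[1:2])
  co2 <- make_cohort(list(list(id = "v", start = 100, end = 200, svtype = "DEL",
                               gt = gt2)), samples)
  expect_equal(unname(cohort_af(co2)), 1 / (2 * (n - 1)))

  co3 <- make_cohort(list(list(id = "v", start = 100, end = 200, svtype = "DEL",
                               gt = setNames(rep("missing", n), samples))), samples)
  expect_error(cohort_af(co3), "no genotyped samples")
})

test_that("AF boundary: 0.1 exactly is retained (transmission headroom), above is excluded", {
  # 10 samples; proband + sequenced offspring het -> AF = 2/20 = 0.1
  ped <- make_ped3()  # 8 samples; add two unrelated founders via a 10th...
  samples <- ped$samples$id
  co <- make_cohort(list(list(
    id = "v", start = 1000, end = 1500, svtype = "DEL",
    gt = c(P1 = "het", P3 = "het"),
    ev = list(ab = c(P1 = 0.5, P3 = 0.5), su = c(P1 = 10, P3 = 9),
              pe = c(P1 = 5, P3 = 5), sr = c(P1 = 5, P3 = 4),
              dhffc = c(P1 = 0.7, P3 = 0.72)))), samples)
  af <- unname(cohort_af(co))
  expect_equal(af, 2 / 16)  # 0.125 > 0.1 -> excluded here
  fc <- filter_cascade(co, ped)
  tr <- fc$trace[fc$trace$filter == "cohort_af", ]
  expect_false(tr$pass[1])
  # widen the cohort so AF is exactly 0.1: retained
  extra <- c("U1", "U2")
  ped2 <- pedigree(rbind(ped$samples,
                         data.frame(family = "line1", id = extra, sire = "0",
                                    dam = "0", sex = 1, phenotype = 0,
                                    line = "line1", tissue = NA)))
  co2 <- make_cohort(list(list(
    id = "v", start = 1000, end = 1500, svtype = "DEL",
    gt = c(P1 = "het", P3 = "het"),
    ev = list(ab = c(P1 = 0.5), su = c(P1 = 10), pe = c(P1 = 5),
              sr = c(P1 = 5), dhffc = c(P1 = 0.7)))), c(samples, extra))
  expect_equal(unname(cohort_af(co2)), 0.1)
  fc2 <- filter_cascade(co2, ped2)
  tr2 <- fc2$trace[fc2$trace$filter == "cohort_af", ]
  expect_true(all(tr2$pass))
})

test_that("type-specific cascades keep every printed inequality strict", {
  th <- default_thresholds()
  pass_del <- type_specific_filter("DEL",
    proband = list(ab = 0.4, su = 10, dhffc = 0.6, dhbfc = 1),
    sire = list(ab = 0, su = 0, dhffc = 0.95, dhbfc = 1),
    dam = list(ab = 0, su = 0, dhffc = 0.93, dhbfc = 1), th)
  expect_true(all(pass_del$pass))

  dup_boundary <- type_specific_filter("DUP",
    proband = list(ab = 0.3, su = 8, dhffc = 1, dhbfc = 1.1),  # exactly 1.1
    sire = list(ab = 0, su = 0, dhffc = 1, dhbfc = 1),
    dam = list(ab = 0, su = 0, dhffc = 1, dhbfc = 1), th)
  expect_false(dup_boundary$pass[dup_boundary$filter == "dhbfc_proband"])

  inv_ok <- type_specific_filter("INV",
    proband = list(ab = 0.25, su = 5, dhffc = 1, dhbfc = 1),
    sire = list(ab = 0.05, su = 1, dhffc = 1, dhbfc = 1),
    dam = list(ab = 0.05, su = 1, dhffc = 1, dhbfc = 1), th)
  expect_true(all(inv_ok$pass))
  inv_low_su <- type_specific_filter("INV",
    proband = list(ab = 0.25, su = 4, dhffc = 1, dhbfc = 1),
    sire = list(ab = 0.05, su = 1, dhffc = 1, dhbfc = 1),
    dam = list(ab = 0.05, su = 1, dhffc = 1, dhbfc = 1), th)
  expect_false(inv_low_su$pass[inv_low_su$filter == "su_proband"])

  # each parent individually bounded: one noisy parent fails the candidate
  noisy_parent <- type_specific_filter("DEL",
    proband = list(ab = 0.4, su = 10, dhffc = 0.6, dhbfc = 1),
    sire = list(ab = 0.3, su = 6, dhffc = 0.95, dhbfc = 1),
    dam = list(ab = 0, su = 0, dhffc = 0.93, dhbfc = 1), th)
  expect_false(noisy_parent$pass[noisy_parent$filter == "ab_sire"])
  expect_false(noisy_parent$pass[noisy_parent$filter == "su_sire"])

  # missing evidence fails the check that needs it
  na_ev <- type_specific_filter("DEL",
    proband = list(ab = 0.4, su = 10, dhffc = NA, dhbfc = 1),
    sire = list(ab = 0, su = 0, dhffc = 0.95, dhbfc = 1),
    dam = list(ab = 0, su = 0, dhffc = 0.93, dhbfc = 1), th)
  expect_false(na_ev$pass[na_ev$filter == "dhffc_proband"])

  expect_error(type_specific_filter("BND", list(), list(), list(), th), "BND")
})

test_that("uniqueness filter removes sites called de novo in multiple probands", {
  base <- data.frame(chrom = "chr3", start = 5000, end = 8000, svtype = "INV",
                     stringsAsFactors = FALSE)
  six <- cbind(base[rep(1, 6), ], proband = sprintf("P%02d", 1:6), id = "inv1")
  one <- data.frame(chrom = "chr4", start = 100, end = 900, svtype = "DEL",
                    proband = "P01", id = "del1", stringsAsFactors = FALSE)
  out <- uniqueness_filter(rbind(six, one))
  expect_equal(out$id, "del1")
  # randomised mixtures agree with a count-by-site oracle, order-free
  set.seed(9)
  for (i in 1:10) {
    n <- 40
    cand <- data.frame(chrom = "chr1",
                       start = sample(1:8, n, replace = TRUE) * 1000,
                       svtype = "DEL", proband = sample(sprintf("P%02d", 1:6),
                                                        n, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand$end <- cand$start + 500
    cand$id <- paste0("s", cand$start)
    cand <- cand[!duplicated(cand[c("id", "proband")]), ]
    cand <- cand[sample(nrow(cand)), ]
    got <- uniqueness_filter(cand)
    nprob <- tapply(cand$proband, cand$id, function(p) length(unique(p)))
    expect_setequal(got$id, names(nprob)[nprob == 1])
  }
})

test_that("tightening any threshold never enlarges the cascade survivor set", {
  ped <- make_ped_n(4)
  co <- random_threshold_cohort(60, ped, seed = 5)
  base <- filter_cascade(co, ped)
  base_keys <- with(base$candidates[base$candidates$status == "candidate", ],
                    paste(id, trio_id))
  tighter <- list(default_thresholds(gq_sum = 140),
                  default_thresholds(af_max = 0.05),
                  default_thresholds(del_dhffc = 0.7, dup_dhbfc = 1.2),
                  default_thresholds(del_ab = 0.1, dup_ab = 0.2, inv_ab = 0.3),
                  default_thresholds(parent_ab = 0.05, parent_su = 1),
                  default_thresholds(del_su = 5, dup_su = 5, inv_su = 7))
  for (th in tighter) {
    got <- filter_cascade(co, ped, th)
    keys <- with(got$candidates[got$candidates$status == "candidate", ],
                 paste(id, trio_id))
    expect_true(all(keys %in% base_keys))
  }
})

test_that("depth QC: proportional counts give r = 1, an outlier sample is flagged excess", {
  ped <- make_ped_n(8)
  samples <- ped$samples$id
  set.seed(21)
  # counts exactly proportional to depth: sample i carries i+3 INV sites at depth 3(i+3)
  depths <- setNames(3 * (seq_along(samples) + 3), samples)
  specs <- list()
  for (i in seq_along(samples)) {
    k <- i + 3
    for (j in seq_len(k)) {
      specs[[length(specs) + 1L]] <- list(
        id = sprintf("i%s_%d", samples[i], j), start = 1000 * (100 * i + j),
        end = 1000 * (100 * i + j) + 500, svtype = "INV",
        gt = setNames("het", samples[i]))
    }
  }
  co <- make_cohort(specs, samples)
  qc <- depth_qc_correlation(co, ped, depths)
  inv <- qc$correlations[qc$correlations$svtype == "INV", ]
  expect_equal(inv$r, 1, tolerance = 1e-6)
  expect_lt(inv$p, 1e-6)

  # one sample with ten times the inversion count of all others -> excess flag
  specs2 <- list()
  for (i in seq_along(samples)) {
    k <- if (i == 3) 40 else 4
    for (j in seq_len(k)) {
      specs2[[length(specs2) + 1L]] <- list(
        id = sprintf("e%s_%d", samples[i], j), start = 1000 * (200 * i + j),
        end = 1000 * (200 * i + j) + 400, svtype = "INV",
        gt = setNames("het", samples[i]))
    }
  }
  co2 <- make_cohort(specs2, samples)
  qc2 <- depth_qc_correlation(co2, ped, depths)
  expect_true(samples[3] %in% qc2$excess$sample)

  # zero variance in counts -> r undefined, reported as NA
  specs3 <- list(list(id = "only", start = 5000, end = 5600, svtype = "DEL",
                      gt = setNames(rep("het", length(samples)), samples)))
  co3 <- make_cohort(specs3, samples)
  qc3 <- depth_qc_correlation(co3, ped, depths)
  expect_true(is.na(qc3$correlations$r[qc3$correlations$svtype == "DEL"]))
})
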