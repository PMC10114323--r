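# Independent oracle implementations kept deliberately naive: straight
# re-statements of the filtering rules, medians and Mendelian logic that the
# package code must agree with.

# sort-based median, no stats::median
brute_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# is a child genotype consistent with its parents' genotypes?
mendel_consistent <- function(child, sire, dam) {
  cnt <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  gametes <- function(g) unique(c(floor(cnt[g] / 2), ceiling(cnt[g] / 2)))
  if (any(c(child, sire, dam) == "missing")) return(TRUE)
  any(outer(gametes(sire), gametes(dam), "+") == cnt[child])
}

# single-function re-implementation of the entire candidate filter cascade
naive_survivors <- function(cohort, ped, th = list(
    gq_sum = 120, af_max = 0.1,
    del_dhffc = 0.8, del_parent_dhffc = 0.8, del_ab = 0.05, del_su = 3,
    dup_dhbfc = 1.1, dup_parent_dhbfc = 1.2, dup_ab = 0.1, dup_su = 3,
    inv_ab = 0.2, inv_su = 5, parent_ab = 0.1, parent_su = 3)) {
  ev <- cohort$evidence
  g <- function(id, s, f) ev[[f]][ev$id == id & ev$sample == s]
  sites <- cohort$sites[!cohort$sites$excluded, , drop = FALSE]
  trios <- ped$trios
  pat <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(trios))) {
      tr <- trios[j, ]
      if (g(sites$id[i], tr$proband, "gt") == "het" &&
          g(sites$id[i], tr$sire, "gt") == "hom_ref" &&
          g(sites$id[i], tr$dam, "gt") == "hom_ref") {
        pat[[length(pat) + 1L]] <- list(i = i, j = j)
      }
    }
  }
  if (!length(pat)) return(data.frame(id = character(0), trio_id = character(0)))
  sitecount <- table(vapply(pat, function(p) sites$id[p$i], character(1)))
  keep <- keep_trio <- character(0)
  for (p in pat) {
    id <- sites$id[p$i]; tr <- trios[p$j, ]
    off <- ped$offspring$offspring[ped$offspring$proband == tr$proband]
    others <- setdiff(cohort$samples, c(tr$sire, tr$dam, tr$proband, off))
    if (any(vapply(others, function(s) g(id, s, "gt") %in% c("het", "hom_alt"),
                   logical(1)))) next
    gqs <- g(id, tr$sire, "gq") + g(id, tr$dam, "gq") + g(id, tr$proband, "gq")
    if (is.na(gqs) || !(gqs > th$gq_sum)) next
    gts <- vapply(cohort$samples, function(s) g(id, s, "gt"), character(1))
    af <- (sum(gts == "het") + 2 * sum(gts == "hom_alt")) /
      (2 * sum(gts != "missing"))
    if (af > th$af_max) next
    pab <- g(id, tr$proband, "ab"); psu <- g(id, tr$proband, "su")
    pm <- function(f) mean(c(g(id, tr$sire, f), g(id, tr$dam, f)))
    ok <- switch(sites$svtype[p$i],
      DEL = isTRUE(g(id, tr$proband, "dhffc") < th$del_dhffc) &&
            isTRUE(pm("dhffc") > th$del_parent_dhffc) &&
            isTRUE(pab > th$del_ab) && isTRUE(psu >= th$del_su),
      DUP = isTRUE(g(id, tr$proband, "dhbfc") > th$dup_dhbfc) &&
            isTRUE(pm("dhbfc") < th$dup_parent_dhbfc) &&
            isTRUE(pab > th$dup_ab) && isTRUE(psu >= th$dup_su),
      INV = isTRUE(pab > th$inv_ab) && isTRUE(psu >= th$inv_su),
      FALSE)
    if (!isTRUE(ok)) next
    if (!(isTRUE(g(id, tr$sire, "ab") < th$parent_ab) &&
          isTRUE(g(id, tr$dam, "ab") < th$parent_ab) &&
          isTRUE(g(id, tr$sire, "su") <= th$parent_su) &&
          isTRUE(g(id, tr$dam, "su") <= th$parent_su))) next
    if (sitecount[[id]] > 1) next
    keep <- c(keep, id); keep_trio <- c(keep_trio, tr$trio_id)
  }
  data.frame(id = keep, trio_id = keep_trio, stringsAsFactors = FALSE)
}

# random cohort whose evidence values straddle every filter threshold
random_threshold_cohort <- function(n_sites, ped, seed) {
  set.seed(seed)
  samples <- ped$samples$id
  trios <- ped$trios
  specs <- lapply(seq_len(n_sites), function(i) {
    svtype <- sample(c("DEL", "DUP", "INV"), 1)
    gt <- character(0)
    for (j in seq_len(nrow(trios))) {
      if (runif(1) < 0.85) gt[trios$proband[j]] <- "het"
      if (runif(1) < 0.05) gt[trios$sire[j]] <- sample(c("het", "missing"), 1)
      if (runif(1) < 0.05) gt[trios$dam[j]] <- "het"
    }
    ev <- list()
    for (sm in samples) {
      ev$ab[sm] <- round(runif(1, 0, 0.3), 3)
      ev$su[sm] <- sample(0:8, 1)
      ev$pe[sm] <- 0; ev$sr[sm] <- 0
      ev$dhffc[sm] <- round(runif(1, 0.5, 1.2), 3)
      ev$dhbfc[sm] <- round(runif(1, 0.8, 1.6), 3)
      ev$gq[sm] <- sample(25:55, 1)
    }
    list(id = sprintf("R%04d", i), start = 1000 + 5000 * i,
         end = 1000 + 5000 * i + 500, svtype = svtype, gt = gt, ev = ev)
  })
  make_cohort(specs, samples)
}
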