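# De novo candidate filtering: Mendelian screen, trio genotype-quality sum,
# cohort allele frequency, per-type evidence thresholds, site uniqueness and
# the depth-correlation QC.

#' Default filter thresholds
#'
#' Every inequality is strict exactly as stated: trio GQ sum `> 120`; cohort
#' allele frequency excluded when `> 0.1`; deletions need proband DHFFC
#' `< 0.8`, parental mean DHFFC `> 0.8` and proband AB `> 0.05`; duplications
#' need proband DHBFC `> 1.1`, parental mean DHBFC `< 1.2` and proband AB
#' `> 0.1`; inversions need proband AB `> 0.2` and at least five supporting
#' reads (three for deletions/duplications); each parent individually must
#' show AB `< 0.1` and at most three supporting reads.
#'
#' @param ... named overrides of any threshold.
#' @export
default_thresholds <- function(...) {
  th <- list(gq_sum = 120, af_max = 0.1,
             del_dhffc = 0.8, del_parent_dhffc = 0.8, del_ab = 0.05, del_su = 3,
             dup_dhbfc = 1.1, dup_parent_dhbfc = 1.2, dup_ab = 0.1, dup_su = 3,
             inv_ab = 0.2, inv_su = 5,
             parent_ab = 0.1, parent_su = 3)
  mod <- list(...)
  bad <- setdiff(names(mod), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(mod)] <- mod
  th
}

carrier_matrix <- function(cohort) {
  gt <- evidence_field(cohort, "gt")
  gt == "het" | gt == "hom_alt"
}

# trio-local de novo genotype pattern: proband het, both parents hom_ref
# (a missing parent genotype disqualifies).  This is the per-trio notion a
# site can satisfy in more than one proband, which the uniqueness filter
# counts; the cohort-wide carrier screen is layered on top.
trio_pattern_candidates <- function(cohort, pedigree) {
  gt <- evidence_field(cohort, "gt")
  sites <- cohort$sites
  use <- !sites$excluded
  out <- lapply(seq_len(nrow(pedigree$trios)), function(i) {
    tr <- pedigree$trios[i, ]
    hit <- use & gt[, tr$proband] == "het" &
      gt[, tr$sire] == "hom_ref" & gt[, tr$dam] == "hom_ref"
    if (!any(hit)) return(NULL)
    data.frame(id = sites$id[hit], trio_id = tr$trio_id,
               proband = tr$proband, sire = tr$sire, dam = tr$dam,
               chrom = sites$chrom[hit], start = sites$start[hit],
               end = sites$end[hit], svtype = sites$svtype[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(0), trio_id = character(0),
                      proband = character(0), sire = character(0),
                      dam = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      svtype = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Mendelian de novo candidate screen
#'
#' Returns (site, trio) pairs where the proband is heterozygous, both
#' parents are homozygous reference, and no other cohort sample carries the
#' variant.  Missing genotypes in parents disqualify (conservative); a
#' missing genotype in an unrelated sample counts as non-carrier.  Sequenced
#' third-generation offspring of the proband are exempt from the carrier
#' screen, since a genuine germline dnSV is expected to be transmitted to
#' about half of them.
#'
#' @param cohort An [sv_cohort()].
#' @param pedigree A [pedigree()].
#' @return data.frame of candidates with an `n_unrelated_carriers` column
#'   (always 0 in the returned rows).
#' @export
mendelian_candidates <- function(cohort, pedigree) {
  cand <- trio_pattern_candidates(cohort, pedigree)
  if (!nrow(cand)) {
    cand$n_unrelated_carriers <- integer(0)
    return(cand)
  }
  cand$n_unrelated_carriers <- unrelated_carrier_count(cohort, pedigree, cand)
  cand[cand$n_unrelated_carriers == 0L, , drop = FALSE]
}

unrelated_carrier_count <- function(cohort, pedigree, cand) {
  C <- carrier_matrix(cohort)
  vapply(seq_len(nrow(cand)), function(k) {
    allowed <- c(cand$proband[k], cand$sire[k], cand$dam[k],
                 offspring_of(pedigree, cand$proband[k]))
    sum(C[cand$id[k], setdiff(cohort$samples, allowed)])
  }, integer(1))
}

#' Trio genotype-quality sum filter
#'
#' Passes when `GQ(sire) + GQ(dam) + GQ(proband)` is strictly greater than
#' the threshold; any missing GQ fails.
#'
#' @param gq_sire,gq_dam,gq_proband numeric vectors of genotype qualities.
#' @param threshold strict lower bound for the sum (default 120).
#' @return data.frame with `gq_sum` and logical `pass`.
#' @export
trio_gq_filter <- function(gq_sire, gq_dam, gq_proband, threshold = 120) {
  s <- gq_sire + gq_dam + gq_proband
  data.frame(gq_sum = s, pass = !is.na(s) & s > threshold)
}

#' Cohort alternate-allele frequency of SV sites
#'
#' `AF = alt allele count / (2 x number of non-missing genotyped samples)`.
#' dnSVs are one-time events, so candidates with AF above `af_max` are
#' excluded downstream; AF equal to the threshold is retained, which leaves
#' room for transmissions to sequenced third-generation offspring.
#'
#' @param cohort An [sv_cohort()].
#' @param id optional site id(s); default all sites.
#' @return Named numeric vector of allele frequencies.
#' @export
cohort_af <- function(cohort, id = NULL) {
  gt <- evidence_field(cohort, "gt")
  if (!is.null(id)) gt <- gt[id, , drop = FALSE]
  alt <- rowSums(gt == "het") + 2L * rowSums(gt == "hom_alt")
  n <- rowSums(gt != "missing")
  if (any(n == 0)) {
    stop("no genotyped samples at site(s): ",
         paste(rownames(gt)[n == 0], collapse = ", "))
  }
  setNames(alt / (2 * n), rownames(gt))
}

# one filter-trace row
trace_row <- function(filter, value, threshold, pass) {
  data.frame(filter = filter, value = as.numeric(value),
             threshold = as.numeric(threshold), pass = pass,
             stringsAsFactors = FALSE)
}

#' Per-type evidence filter for one candidate
#'
#' Applies the deletion, duplication or inversion threshold cascade to the
#' proband and parent evidence of one candidate.  All inequalities are
#' strict as stated in [default_thresholds()]; missing values fail the check
#' that needs them.
#'
#' @param svtype one of `"DEL"`, `"DUP"`, `"INV"` (`"BND"` is an error;
#'   breakends are excluded upstream).
#' @param proband,sire,dam lists (or one-row data.frames) with elements
#'   `ab`, `su`, `dhffc`, `dhbfc`.
#' @param thresholds see [default_thresholds()].
#' @return data.frame filter trace (`filter`, `value`, `threshold`, `pass`).
#' @export
type_specific_filter <- function(svtype, proband, sire, dam,
                                 thresholds = default_thresholds()) {
  th <- thresholds
  lt <- function(v, t) !is.na(v) & v < t
  gt_ <- function(v, t) !is.na(v) & v > t
  le <- function(v, t) !is.na(v) & v <= t
  ge <- function(v, t) !is.na(v) & v >= t
  parent_mean <- function(field) {
    v <- c(sire[[field]], dam[[field]])
    if (any(is.na(v))) NA_real_ else mean(v)
  }
  rows <- switch(svtype,
    DEL = rbind(
      trace_row("dhffc_proband", proband$dhffc, th$del_dhffc, lt(proband$dhffc, th$del_dhffc)),
      trace_row("dhffc_parent_mean", parent_mean("dhffc"), th$del_parent_dhffc,
                gt_(parent_mean("dhffc"), th$del_parent_dhffc)),
      trace_row("ab_proband", proband$ab, th$del_ab, gt_(proband$ab, th$del_ab)),
      trace_row("su_proband", proband$su, th$del_su, ge(proband$su, th$del_su))),
    DUP = rbind(
      trace_row("dhbfc_proband", proband$dhbfc, th$dup_dhbfc, gt_(proband$dhbfc, th$dup_dhbfc)),
      trace_row("dhbfc_parent_mean", parent_mean("dhbfc"), th$dup_parent_dhbfc,
                lt(parent_mean("dhbfc"), th$dup_parent_dhbfc)),
      trace_row("ab_proband", proband$ab, th$dup_ab, gt_(proband$ab, th$dup_ab)),
      trace_row("su_proband", proband$su, th$dup_su, ge(proband$su, th$dup_su))),
    INV = rbind(
      trace_row("ab_proband", proband$ab, th$inv_ab, gt_(proband$ab, th$inv_ab)),
      trace_row("su_proband", proband$su, th$inv_su, ge(proband$su, th$inv_su))),
    stop("type-specific filters apply to DEL/DUP/INV only, got ", svtype)
  )
  rbind(rows,
        trace_row("ab_sire", sire$ab, th$parent_ab, lt(sire$ab, th$parent_ab)),
        trace_row("ab_dam", dam$ab, th$parent_ab, lt(dam$ab, th$parent_ab)),
        trace_row("su_sire", sire$su, th$parent_su, le(sire$su, th$parent_su)),
        trace_row("su_dam", dam$su, th$parent_su, le(dam$su, th$parent_su)))
}

#' Remove candidate sites called de novo in more than one proband
#'
#' Identical dnSVs found in multiple probands are expected to be false
#' positives because a de novo mutation is a one-time event: every candidate
#' whose site (same chrom/start/end/svtype) is a de novo candidate in more
#' than one proband is removed.
#'
#' @param candidates data.frame with columns `chrom`, `start`, `end`,
#'   `svtype`, `proband`.
#' @return The surviving subset of `candidates`.
#' @export
uniqueness_filter <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  key <- site_key(candidates)
  np <- tapply(candidates$proband, key, function(p) length(unique(p)))
  candidates[np[key] == 1L, , drop = FALSE]
}

site_key <- function(x) paste(x$chrom, x$start, x$end, x$svtype, sep = ":")

#' Full de novo candidate filter cascade
#'
#' Applies, per trio-local candidate: the cohort-wide carrier screen, the
#' trio GQ-sum filter, the cohort allele-frequency filter, the per-type
#' evidence cascade, and the site-uniqueness filter.  Every filter is a pure
#' predicate of the cohort, so the surviving set does not depend on
#' application order; all checks are always evaluated and recorded.
#'
#' @inheritParams mendelian_candidates
#' @param thresholds see [default_thresholds()].
#' @return list with `candidates` (one row per trio-local candidate with
#'   `status` `"candidate"`/`"rejected"`) and `trace` (long data.frame of
#'   every check: `id`, `trio_id`, `filter`, `value`, `threshold`, `pass`).
#' @export
filter_cascade <- function(cohort, pedigree, thresholds = default_thresholds()) {
  cand <- trio_pattern_candidates(cohort, pedigree)
  empty_trace <- data.frame(id = character(0), trio_id = character(0),
                            filter = character(0), value = numeric(0),
                            threshold = numeric(0), pass = logical(0))
  if (!nrow(cand)) {
    cand$status <- character(0)
    return(list(candidates = cand, trace = empty_trace,
                thresholds = thresholds))
  }
  af <- cohort_af(cohort)
  gq <- evidence_field(cohort, "gq")
  ev_of <- function(id, sample) {
    lapply(setNames(c("ab", "su", "dhffc", "dhbfc"),
                    c("ab", "su", "dhffc", "dhbfc")),
           function(f) evidence_field(cohort, f)[id, sample])
  }
  n_unrel <- unrelated_carrier_count(cohort, pedigree, cand)
  key <- site_key(cand)
  n_prob <- tapply(cand$proband, key, function(p) length(unique(p)))[key]
  traces <- lapply(seq_len(nrow(cand)), function(k) {
    id <- cand$id[k]
    tr <- rbind(
      trace_row("unrelated_carriers", n_unrel[k], 0, n_unrel[k] == 0L),
      {
        g <- trio_gq_filter(gq[id, cand$sire[k]], gq[id, cand$dam[k]],
                            gq[id, cand$proband[k]], thresholds$gq_sum)
        trace_row("gq_sum", g$gq_sum, thresholds$gq_sum, g$pass)
      },
      trace_row("cohort_af", af[id], thresholds$af_max, af[id] <= thresholds$af_max),
      type_specific_filter(cand$svtype[k], ev_of(id, cand$proband[k]),
                           ev_of(id, cand$sire[k]), ev_of(id, cand$dam[k]),
                           thresholds),
      trace_row("unique_site", n_prob[k], 1, n_prob[k] <= 1L))
    cbind(id = id, trio_id = cand$trio_id[k], tr)
  })
  trace <- do.call(rbind, traces)
  # recurrent sites share ids across trios; aggregate per (id, trio)
  keyc <- paste(trace$id, trace$trio_id, sep = "\r")
  ok <- tapply(trace$pass, keyc, all)
  cand$status <- ifelse(ok[paste(cand$id, cand$trio_id, sep = "\r")],
                        "candidate", "rejected")
  first_fail <- vapply(seq_len(nrow(cand)), function(k) {
    rows <- trace[trace$id == cand$id[k] & trace$trio_id == cand$trio_id[k], ]
    f <- rows$filter[!rows$pass]
    if (length(f)) f[1] else NA_character_
  }, character(1))
  cand$failed_filter <- first_fail
  list(candidates = cand, trace = trace, thresholds = thresholds)
}

#' Depth-correlation quality control
#'
#' Per line and SV type, the Pearson correlation (with two-sided p-value)
#' between each sample's mean sequencing depth and its count of called SVs;
#' systematic positive correlations indicate depth-driven false calls.
#' Samples whose per-type count exceeds `median + mad_mult * MAD` within
#' their line are flagged as showing an excess of candidate calls.
#'
#' @param cohort An [sv_cohort()].
#' @param pedigree A [pedigree()] (supplies the line labels).
#' @param sample_depths named numeric vector of mean depth per sample.
#' @param mad_mult MAD multiplier for the excess flag (default 3).
#' @return list with `correlations` (line, svtype, n, r, p) and `excess`
#'   (line, svtype, sample, count, cutoff).
#' @export
depth_qc_correlation <- function(cohort, pedigree, sample_depths, mad_mult = 3) {
  C <- carrier_matrix(cohort)
  lines <- pedigree$samples$line[match(cohort$samples, pedigree$samples$id)]
  res <- NULL
  exc <- NULL
  for (ln in unique(lines)) {
    ids <- cohort$samples[lines == ln]
    if (length(ids) < 3) next
    d <- sample_depths[ids]
    for (tp in intersect(SV_TYPES, unique(cohort$sites$svtype))) {
      cnt <- colSums(C[cohort$sites$svtype == tp, ids, drop = FALSE])
      if (stats::sd(d) == 0 || stats::sd(cnt) == 0) {
        res <- rbind(res, data.frame(line = ln, svtype = tp, n = length(ids),
                                     r = NA_real_, p = NA_real_))
      } else {
        ct <- stats::cor.test(d, cnt)
        res <- rbind(res, data.frame(line = ln, svtype = tp, n = length(ids),
                                     r = unname(ct$estimate), p = ct$p.value))
      }
      cut <- stats::median(cnt) + mad_mult * stats::mad(cnt)
      hit <- cnt > cut
      if (any(hit)) {
        exc <- rbind(exc, data.frame(line = ln, svtype = tp,
                                     sample = ids[hit], count = cnt[hit],
                                     cutoff = cut))
      }
    }
  }
  if (is.null(exc)) {
    exc <- data.frame(line = character(0), svtype = character(0),
                      sample = character(0), count = numeric(0),
                      cutoff = numeric(0))
  }
  list(correlations = res, excess = exc)
}
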