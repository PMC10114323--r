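# End-to-end orchestration: callset -> Mendelian/quality/type filters ->
# breakpoint evidence review -> characterisation -> rate estimate.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default: the filter
#' thresholds ([default_thresholds()]), the review rules
#' ([review_config()]), the mutation clustering window, the confidence
#' level of the rate interval, the germline-zygosity tolerance on the
#' deleted-DNA fraction, and the 2:1-ratio band for duplication phasing.
#'
#' @param thresholds see [default_thresholds()].
#' @param review see [review_config()].
#' @param cluster_window single-linkage clustering window in bp
#'   (default 50 kb, spanning both compact and complex observed clusters).
#' @param conf confidence level of the Wilson rate interval.
#' @param germline_delta tolerance on `d = 0.5` for germline zygosity.
#' @param dup_minor_band accepted pooled minor-read fraction for a 2:1
#'   duplication ratio.
#' @param homology_flank flank length for junction homology (bp).
#' @export
pipeline_config <- function(thresholds = default_thresholds(),
                            review = review_config(),
                            cluster_window = 50000L,
                            conf = 0.95,
                            germline_delta = 0.1,
                            dup_minor_band = c(0.28, 0.40),
                            homology_flank = 20L) {
  list(thresholds = thresholds, review = review,
       cluster_window = as.integer(cluster_window), conf = conf,
       germline_delta = germline_delta, dup_minor_band = dup_minor_band,
       homology_flank = as.integer(homology_flank))
}

#' Run the dnSV discovery and characterisation pipeline
#'
#' Stages: (1) drop breakend records; (2) the candidate filter cascade
#' ([filter_cascade()]); (3) breakpoint evidence review
#' ([review_candidates()]); (4) characterisation of every high-evidence
#' dnSV — parent of origin, junction homology and mechanism, clustering,
#' genic context, zygosity from het-SNP ratios, transmission in sequenced
#' offspring; (5) the per-generation rate over germline dnSV events
#' (clustered mutations count once; mosaic calls are excluded).
#'
#' Deterministic given its inputs; every trio-local candidate appears
#' exactly once in the rejection trace or the confirmed set.
#'
#' @param cohort An [sv_cohort()].
#' @param pedigree A [pedigree()].
#' @param config A [pipeline_config()].
#' @param bp_evidence,repeats,profiles,snvs,reference,genes optional
#'   evidence layers; stages needing an absent layer degrade conservatively
#'   (review without breakpoint evidence rejects; characterisation fields
#'   fall back to `unknown`/`NA`).
#' @param dnsnvs optional data.frame of de novo point mutations
#'   (`id`, `chrom`, `start`, `end`, `length`) co-clustered with the dnSVs.
#' @param sample_depths optional named depth vector for the depth QC.
#' @return Object of class `dnsv_result`.
#' @export
run_pipeline <- function(cohort, pedigree, config = pipeline_config(),
                         bp_evidence = NULL, repeats = NULL, profiles = NULL,
                         snvs = NULL, reference = NULL, genes = NULL,
                         dnsnvs = NULL, sample_depths = NULL) {
  casc <- filter_cascade(cohort, pedigree, config$thresholds)
  cand <- casc$candidates
  surv <- cand[cand$status == "candidate", , drop = FALSE]
  rev <- review_candidates(surv, bp_evidence, repeats, profiles, config$review)
  conf_rows <- rev[rev$verdict == "high_evidence", , drop = FALSE]

  characterisations <- characterise_dnsvs(conf_rows, cohort, pedigree, config,
                                          snvs, reference, genes)
  # mutation clusters are single-individual events: cluster per proband
  germ <- characterisations[characterisations$zygosity != "mosaic", , drop = FALSE]
  clus_in <- data.frame(id = germ$id, chrom = germ$chrom, start = germ$start,
                        end = germ$end, length = germ$size,
                        proband = germ$proband, stringsAsFactors = FALSE)
  if (!is.null(dnsnvs) && nrow(dnsnvs)) {
    clus_in <- rbind(clus_in,
                     data.frame(id = dnsnvs$id, chrom = dnsnvs$chrom,
                                start = dnsnvs$start, end = dnsnvs$end,
                                length = if (is.null(dnsnvs$length)) 1L else dnsnvs$length,
                                proband = if (is.null(dnsnvs$proband)) NA_character_ else dnsnvs$proband,
                                stringsAsFactors = FALSE))
  }
  members <- NULL
  clusters <- NULL
  offset <- 0L
  for (pb in unique(clus_in$proband)) {
    sub <- clus_in[if (is.na(pb)) is.na(clus_in$proband) else
                   !is.na(clus_in$proband) & clus_in$proband == pb, , drop = FALSE]
    cl <- cluster_dnms(sub, config$cluster_window)
    cl$members$cluster_id <- cl$members$cluster_id + offset
    cl$clusters$cluster_id <- cl$clusters$cluster_id + offset
    offset <- offset + nrow(cl$clusters)
    members <- rbind(members, cl$members)
    clusters <- rbind(clusters, cl$clusters)
  }
  if (is.null(clusters)) {
    cl0 <- cluster_dnms(clus_in[, setdiff(names(clus_in), "proband")],
                        config$cluster_window)
    members <- cl0$members; clusters <- cl0$clusters
  }
  characterisations$cluster <- members$cluster_id[match(characterisations$id,
                                                        members$id)]
  n_events <- nrow(clusters)
  rate <- estimate_rate(n_events, nrow(pedigree$trios), config$conf)
  qc <- if (!is.null(sample_depths)) {
    depth_qc_correlation(cohort, pedigree, sample_depths)
  }
  structure(list(candidates = cand, trace = casc$trace, review = rev,
                 confirmed = characterisations, clusters = clusters,
                 rate = rate, qc = qc,
                 n_trios = nrow(pedigree$trios),
                 n_sites = nrow(cohort$sites),
                 n_candidates = nrow(surv)),
            class = "dnsv_result")
}

characterise_dnsvs <- function(conf_rows, cohort, pedigree, config,
                               snvs, reference, genes) {
  n <- nrow(conf_rows)
  out <- data.frame(id = conf_rows$id, trio_id = conf_rows$trio_id,
                    proband = conf_rows$proband, svtype = conf_rows$svtype,
                    chrom = conf_rows$chrom, start = conf_rows$start,
                    end = conf_rows$end,
                    size = conf_rows$end - conf_rows$start,
                    stringsAsFactors = FALSE)
  out$parent_of_origin <- rep("unknown", n)
  out$homology_len <- rep(NA_integer_, n)
  out$mechanism <- rep("unresolved", n)
  out$locus <- rep(NA_character_, n)
  out$genic_context <- rep(NA_character_, n)
  out$intron <- rep(NA_character_, n)
  out$zygosity <- rep("germline", n)
  out$deleted_fraction <- rep(NA_real_, n)
  out$transmission <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    sv <- as.list(conf_rows[k, c("chrom", "start", "end", "svtype")])
    trio <- as.list(pedigree$trios[pedigree$trios$proband == conf_rows$proband[k], ])
    if (!is.null(snvs) && nrow(snvs)) {
      out$parent_of_origin[k] <- assign_parent_of_origin(
        sv, snvs[snvs$sample %in% c(trio$sire, trio$dam, trio$proband), ],
        trio, dup_minor_band = config$dup_minor_band)
      if (sv$svtype == "DEL") {
        pr <- snvs[snvs$sample == conf_rows$proband[k] &
                   snvs$chrom == sv$chrom &
                   snvs$pos > sv$start & snvs$pos <= sv$end, , drop = FALSE]
        if (nrow(pr)) {
          mf <- mosaic_fraction(pr$ref_reads, pr$alt_reads,
                                delta = config$germline_delta)
          out$zygosity[k] <- mf$zygosity
          out$deleted_fraction[k] <- mf$d
        }
      }
    }
    if (!is.null(reference)) {
      h <- junction_homology(reference, sv, flank = config$homology_flank)
      out$homology_len[k] <- h
      out$mechanism[k] <- classify_mechanism(h)
    }
    if (!is.null(genes) && length(genes)) {
      g <- genic_context(sv, genes)
      out$genic_context[k] <- g$context
      out$locus[k] <- paste(g$gene_ids, collapse = ",")
      out$intron[k] <- g$intron
    }
    out$transmission[k] <- check_transmission(conf_rows$id[k],
                                              conf_rows$proband[k],
                                              cohort, pedigree)
  }
  out
}

#' @export
print.dnsv_result <- function(x, ...) {
  cat("dnSV pipeline result\n")
  cat("  sites analysed:     ", x$n_sites, "\n")
  cat("  cascade candidates: ", x$n_candidates, " (of ",
      nrow(x$candidates), " trio-local)\n", sep = "")
  cat("  confirmed dnSVs:    ", nrow(x$confirmed), "\n")
  cat("  de novo events:     ", x$rate$k, "\n")
  print(x$rate)
  if (x$n_candidates > 0) {
    cat(sprintf("  spurious candidates: %.1f%%\n",
                spurious_rate(x$n_candidates, nrow(x$confirmed))))
  }
  invisible(x)
}
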