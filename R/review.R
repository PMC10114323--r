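# Rule-based review of breakpoint-local evidence: an automated, testable
# proxy for manual inspection of candidate dnSVs in a genome browser.

#' Review configuration
#'
#' @param repeat_window half-width (bp) of the breakpoint window intersected
#'   with repeat intervals (default 50).
#' @param min_support minimum split + discordant-pair reads required at each
#'   breakpoint (default 3).
#' @param del_step,dup_step coverage-step thresholds: a deletion breakpoint
#'   shows a real shift when its interior/exterior depth ratio is `<=`
#'   `del_step`, a duplication when it is `>=` `dup_step`.  Defaults reuse
#'   the cascade's fold-change cutoffs (0.8 and 1.1) as proxies for a
#'   "clear visual" change.
#' @param step_window window width (bp) for the coverage step
#'   (see [breakpoint_steps()]).
#' @export
review_config <- function(repeat_window = 50L, min_support = 3L,
                          del_step = 0.8, dup_step = 1.1, step_window = 500L) {
  list(repeat_window = as.integer(repeat_window),
       min_support = as.integer(min_support),
       del_step = del_step, dup_step = dup_step,
       step_window = as.integer(step_window))
}

# do any of the supplied read intervals overlap pairwise?
reads_overlap <- function(reads) {
  if (is.null(reads) || nrow(reads) < 2) return(NA)
  o <- order(reads$start)
  s <- reads$start[o]; e <- reads$end[o]
  any(s[-1] <= cummax(e)[-length(e)])
}

repeat_hit <- function(repeats, chrom, pos, w) {
  if (is.null(repeats) || !nrow(repeats)) return(FALSE)
  any(repeats$chrom == chrom & repeats$start <= pos + w & repeats$end >= pos - w)
}

#' Review one candidate dnSV against breakpoint-local evidence
#'
#' Encodes five rejection rules; a candidate is `spurious` when any rule is
#' violated, `high_evidence` otherwise:
#' \enumerate{
#'   \item both breakpoints overlap repeat intervals (within
#'     `repeat_window` bp);
#'   \item only one breakpoint has split-read or discordant-pair support;
#'   \item fewer than `min_support` supporting reads at either breakpoint;
#'   \item the supporting-read intervals at a breakpoint are pairwise
#'     disjoint (no position covered twice);
#'   \item no coverage decrease (deletions) or increase (duplications) at
#'     both breakpoints.  Inversions change no copy number, so rules 1--4
#'     only.
#' }
#' Missing evidence for a breakpoint is treated as absent support
#' (rule 2/3), conservatively.
#'
#' @param svtype `"DEL"`, `"DUP"` or `"INV"`.
#' @param chrom chromosome of the candidate.
#' @param breakpoints numeric length-2: left and right breakpoint positions.
#' @param evidence list with elements `left` and `right`, each a list with
#'   `sr`, `pe` (counts) and `reads` (data.frame `start`, `end` of
#'   supporting-read intervals); either side may be `NULL`.
#' @param repeats repeat intervals (data.frame `chrom`, `start`, `end`,
#'   1-based closed; see [read_repeats()]), or `NULL`.
#' @param steps optional named vector `c(left =, right =)` of breakpoint
#'   coverage steps (see [breakpoint_steps()]); `NA`/missing steps count as
#'   "no visible shift".
#' @param config see [review_config()].
#' @return list with `verdict` (`"high_evidence"` or `"spurious"`),
#'   `violated` (integer rule ids) and `checks` (per-rule data.frame).
#' @export
review_candidate <- function(svtype, chrom, breakpoints, evidence,
                             repeats = NULL, steps = NULL,
                             config = review_config()) {
  stopifnot(svtype %in% c("DEL", "DUP", "INV"), length(breakpoints) == 2)
  side <- function(x) if (is.null(x)) list(sr = 0L, pe = 0L, reads = NULL) else x
  L <- side(evidence$left); R <- side(evidence$right)
  supp <- function(s) sum(s$sr, s$pe, na.rm = TRUE)

  r1 <- repeat_hit(repeats, chrom, breakpoints[1], config$repeat_window) &&
        repeat_hit(repeats, chrom, breakpoints[2], config$repeat_window)
  r2 <- (supp(L) > 0) != (supp(R) > 0)
  r3 <- supp(L) < config$min_support || supp(R) < config$min_support
  ov <- c(reads_overlap(L$reads), reads_overlap(R$reads))
  r4 <- any(!ov, na.rm = TRUE)
  if (svtype == "INV") {
    r5 <- FALSE
  } else {
    st <- c(left = NA_real_, right = NA_real_)
    if (!is.null(steps)) st[names(steps)] <- steps
    shift <- if (svtype == "DEL") !is.na(st) & st <= config$del_step
             else !is.na(st) & st >= config$dup_step
    r5 <- !any(shift)
  }
  flags <- c(r1, r2, r3, r4, r5)
  checks <- data.frame(rule = 1:5,
                       description = c("both breakpoints in repeats",
                                       "one-sided support",
                                       "insufficient support at a breakpoint",
                                       "supporting reads mutually disjoint",
                                       "no coverage shift at the breakpoints"),
                       violated = flags)
  list(verdict = if (any(flags)) "spurious" else "high_evidence",
       violated = which(flags), checks = checks)
}

#' Review a table of candidates
#'
#' Applies [review_candidate()] to each surviving cascade candidate, taking
#' per-breakpoint read evidence from `bp_evidence` (a named list by site id)
#' and measuring coverage steps on the proband's depth profile when
#' available.  Candidates without breakpoint evidence are spurious via the
#' one-sided-support rule.
#'
#' @param candidates data.frame with columns `id`, `trio_id`, `proband`,
#'   `chrom`, `start`, `end`, `svtype`.
#' @param bp_evidence named list: `bp_evidence[[id]]` is the
#'   `list(left =, right =)` evidence of [review_candidate()].
#' @param repeats repeat intervals or `NULL`.
#' @param profiles nested list `profiles[[sample]][[chrom]]` of
#'   [depth_profile()]s, or `NULL`.
#' @param config see [review_config()].
#' @return `candidates` with `verdict` and `violated_rules` (comma-joined)
#'   columns appended.
#' @export
review_candidates <- function(candidates, bp_evidence, repeats = NULL,
                              profiles = NULL, config = review_config()) {
  n <- nrow(candidates)
  verdict <- character(n); rules <- character(n)
  for (k in seq_len(n)) {
    id <- candidates$id[k]
    steps <- NULL
    prof <- profiles[[candidates$proband[k]]][[candidates$chrom[k]]]
    if (!is.null(prof)) {
      steps <- breakpoint_steps(prof, candidates$start[k], candidates$end[k],
                                config$step_window)
    }
    r <- review_candidate(candidates$svtype[k], candidates$chrom[k],
                          c(candidates$start[k], candidates$end[k]),
                          evidence = if (is.null(bp_evidence[[id]])) list() else bp_evidence[[id]],
                          repeats = repeats, steps = steps, config = config)
    verdict[k] <- r$verdict
    rules[k] <- paste(r$violated, collapse = ",")
  }
  candidates$verdict <- verdict
  candidates$violated_rules <- rules
  candidates
}
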