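# Small hand-built cohorts and pedigrees used across tests.

# three trios; P1 is reused as the sire of trio 3, so P3 is a sequenced
# third-generation offspring of P1
make_ped3 <- function() {
  pedigree(data.frame(
    family = "line1",
    id   = c("S1", "S2", "D1", "D2", "D3", "P1", "P2", "P3"),
    sire = c("0", "0", "0", "0", "0", "S1", "S2", "P1"),
    dam  = c("0", "0", "0", "0", "0", "D1", "D2", "D3"),
    sex = c(1, 1, 2, 2, 2, 1, 2, 1), phenotype = 0,
    stringsAsFactors = FALSE))
}

# n independent trios (no third-generation links)
make_ped_n <- function(n, line = "line1") {
  ids <- sprintf("%s%02d", rep(c("S", "D", "P"), each = n), rep(seq_len(n), 3))
  s <- sprintf("S%02d", seq_len(n)); d <- sprintf("D%02d", seq_len(n))
  p <- sprintf("P%02d", seq_len(n))
  pedigree(data.frame(
    family = line,
    id = c(s, d, p),
    sire = c(rep("0", 2 * n), s),
    dam = c(rep("0", 2 * n), d),
    sex = c(rep(1, n), rep(2, n), rep(1, n)), phenotype = 0,
    stringsAsFactors = FALSE))
}

# default per-sample evidence for a non-carrier
.default_ev <- list(gq = 60, ab = 0, su = 0, pe = 0, sr = 0, dhffc = 1, dhbfc = 1)
# evidence of a clean heterozygous carrier
carrier_ev <- list(ab = 0.5, su = 10, pe = 5, sr = 5, dhffc = 0.75, dhbfc = 1.25)

# Build an sv_cohort from site specs.  Each spec: list(id, start, end, svtype,
# chrom = "chr1", gt = named character vector of non-hom_ref genotypes,
# ev = named list field -> named numeric vector of per-sample overrides).
make_cohort <- function(specs, samples) {
  sites <- do.call(rbind, lapply(specs, function(s) data.frame(
    id = s$id, chrom = if (is.null(s$chrom)) "chr1" else s$chrom,
    start = s$start, end = s$end, svtype = s$svtype,
    stringsAsFactors = FALSE)))
  rows <- list()
  for (s in specs) {
    for (sm in samples) {
      r <- c(list(id = s$id, sample = sm,
                  gt = if (!is.null(s$gt) && sm %in% names(s$gt))
                         unname(s$gt[[sm]]) else "hom_ref"),
             .default_ev)
      if (!is.null(s$ev)) {
        for (f in names(s$ev)) {
          if (sm %in% names(s$ev[[f]])) r[[f]] <- unname(s$ev[[f]][[sm]])
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(r, stringsAsFactors = FALSE)
    }
  }
  sv_cohort(sites, do.call(rbind, rows), samples)
}

# spread one evidence list over several samples
ev_for <- function(ev, samples) {
  lapply(ev, function(v) setNames(rep(v, length(samples)), samples))
}

# merge per-sample evidence override lists
ev_merge <- function(...) {
  parts <- list(...)
  out <- list()
  for (p in parts) for (f in names(p)) out[[f]] <- c(out[[f]], p[[f]])
  out
}

# small deterministic random reference chromosome
random_reference <- function(len = 3000, seed = 1, chrom = "chr1") {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), chrom)
}

# strong two-sided breakpoint read evidence for review tests
strong_bp <- function(left_bp, right_bp, n = 6) {
  side <- function(bp) {
    starts <- bp - seq(20, 20 + 15 * (n - 1), by = 15)
    list(sr = ceiling(n / 2), pe = floor(n / 2),
         reads = data.frame(start = starts, end = starts + 149))
  }
  list(left = side(left_bp), right = side(right_bp))
}
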