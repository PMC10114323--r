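# Pedigree-structured synthetic SV cohorts with planted ground truth.
#
# The generator emulates the data a trio-based dnSV study works from: a
# two-line cohort of deeply sequenced sire-dam-proband trios (some probands
# reused as sires, giving sequenced third-generation offspring), a
# population SV callset with per-sample genotyping evidence, per-proband
# binned depth profiles, informative SNPs inside SVs with known parental
# phase, junction sequences with controlled breakpoint homology, a repeat
# annotation and simple gene models.  Planted variant classes: Mendelian-
# consistent inherited polymorphisms, true de novo SVs (het in one proband,
# absent everywhere else), mosaic SVs with attenuated evidence, and false
# positives engineered to trip one specific filter or review rule each.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: two commercial lines of
#' 20 trios each at ~30x depth, 10 strong de novo SVs, 200 inherited
#' polymorphic SVs, 2 mosaic SVs and 50 false positives cycling through all
#' seven failure modes.  Carrier evidence is centred at allelic balance
#' `0.5 m`, deletion fold-change `1 - m/4` and duplication fold-change
#' `1 + m/4` for a heterozygous carrier with cell fraction `m` (1 for
#' germline), with tight dispersions matching median-based summaries of 30x
#' coverage.  The seed fixes the full output.
#'
#' @param seed integer RNG seed.
#' @param n_trios_per_line trios per line (two lines).
#' @param mean_depth,depth_sd per-sample mean sequencing depth model.
#' @param n_de_novo,n_inherited,n_mosaic,n_false_positive planted counts.
#' @param sv_size_range SV length range in bp (log-uniform).
#' @param svtype_probs sampling weights for DEL/DUP/INV among de novo and
#'   inherited SVs.
#' @param homology_weights length-16 weights for planted breakpoint
#'   homology 0..15 bp (default: mostly 0-1 bp, i.e. non-homology based).
#' @param mosaic_m mosaic cell fraction for planted mosaic SVs.
#' @param snp_spacing spacing of informative SNPs planted inside SVs (bp).
#' @param ab_concentration Beta concentration of carrier allelic balance.
#' @param fold_sd s.d. of the depth fold-change evidence fields.
#' @param noise_su_mean mean spurious supporting reads in non-carriers.
#' @param su_fraction fraction of carrier-haplotype fragments registering
#'   as supporting reads.
#' @param gq_mean,gq_sd,gq_max genotype-quality model.
#' @param n_chrom,chrom_length,bin_size genome layout (must satisfy
#'   `chrom_length %% bin_size == 0`).
#' @param n_third_gen number of line-1 probands reused as sires (their
#'   trios provide sequenced third-generation offspring).
#' @param n_transmitted number of de novo SVs transmitted to a sequenced
#'   offspring.
#' @param recurrent_copies probands sharing each recurrent false-positive
#'   site.
#' @export
sim_config <- function(seed = 1L,
                       n_trios_per_line = 20L,
                       mean_depth = 30, depth_sd = 2,
                       n_de_novo = 10L, n_inherited = 200L,
                       n_mosaic = 2L, n_false_positive = 50L,
                       sv_size_range = c(150L, 5000L),
                       svtype_probs = c(DEL = 0.5, DUP = 0.3, INV = 0.2),
                       homology_weights = c(0.40, 0.15, rep(0.45 / 14, 14)),
                       mosaic_m = 0.5,
                       snp_spacing = 300L,
                       ab_concentration = 80,
                       fold_sd = 0.01,
                       noise_su_mean = 0.2,
                       su_fraction = 1,
                       gq_mean = 60, gq_sd = 8, gq_max = 99,
                       n_chrom = 6L, chrom_length = 400000L, bin_size = 100L,
                       n_third_gen = 4L, n_transmitted = 2L,
                       recurrent_copies = 3L) {
  stopifnot(n_trios_per_line > n_third_gen, chrom_length %% bin_size == 0,
            length(homology_weights) == 16, mosaic_m > 0, mosaic_m <= 1,
            sv_size_range[1] >= 100, sv_size_range[2] >= sv_size_range[1],
            all(c(n_de_novo, n_inherited, n_mosaic, n_false_positive) >= 0))
  n_transmitted <- min(n_transmitted, n_third_gen, n_de_novo)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

sim_pedigree <- function(cfg) {
  npl <- cfg$n_trios_per_line
  n_trio <- 2L * npl
  j <- seq_len(n_trio)
  line <- ifelse(j <= npl, "line1", "line2")
  proband <- sprintf("P%02d", j)
  dam <- sprintf("D%02d", j)
  sire <- sprintf("S%02d", j)
  # last n_third_gen line-1 trios reuse early line-1 probands as sires
  reuse <- (npl - cfg$n_third_gen + 1L):npl
  sire[reuse] <- sprintf("P%02d", seq_len(cfg$n_third_gen))
  founders_s <- setdiff(sire, proband)
  tissue2 <- c("ear", "hair", "semen")
  rows <- rbind(
    data.frame(family = "line1", id = founders_s[founders_s %in% sire[j <= npl]],
               sire = "0", dam = "0", sex = 1L, phenotype = 0L,
               stringsAsFactors = FALSE),
    data.frame(family = "line2", id = founders_s[founders_s %in% sire[j > npl]],
               sire = "0", dam = "0", sex = 1L, phenotype = 0L,
               stringsAsFactors = FALSE),
    data.frame(family = line, id = dam, sire = "0", dam = "0", sex = 2L,
               phenotype = 0L, stringsAsFactors = FALSE),
    data.frame(family = line, id = proband, sire = sire, dam = dam,
               sex = rep_len(c(1L, 2L), n_trio), phenotype = 0L,
               stringsAsFactors = FALSE))
  rows$sex[rows$id %in% sprintf("P%02d", seq_len(cfg$n_third_gen))] <- 1L
  rows$line <- rows$family
  rows$tissue <- ifelse(rows$line == "line1", "ear",
                        tissue2[1L + (seq_len(nrow(rows)) %% 3L)])
  pedigree(rows)
}

# deterministic mode -> svtype used for planted false positives
fp_svtype <- c(repeat_both_breakpoints = "DEL", one_sided_support = "DEL",
               low_read_support = "DUP", non_overlapping_reads = "DEL",
               no_coverage_shift = "DEL", parental_evidence = "DEL",
               recurrent_in_cohort = "INV")

#' Simulate a pedigree-structured SV cohort with planted truth
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_cohort`: a list with `cohort`
#'   ([sv_cohort()]), `pedigree`, `truth` (one row per planted SV:
#'   `id`, `class`, `failure_mode`, `origin`, `homology_len`, `m`,
#'   `proband`, `transmitted`, coordinates), `profiles` (per-proband,
#'   per-chromosome [depth_profile()]s), `snvs` (informative SNPs),
#'   `bp_evidence` (per-site breakpoint read evidence), `repeats`,
#'   `genes` (`GRanges` gene models), `reference`
#'   (`Biostrings::DNAStringSet`), `sample_depths` and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  ped <- sim_pedigree(cfg)
  samples <- ped$samples$id
  trios <- ped$trios
  probands <- trios$proband

  ## ---- plan the planted SVs -------------------------------------------
  classes <- c(rep("de_novo", cfg$n_de_novo), rep("inherited", cfg$n_inherited),
               rep("mosaic", cfg$n_mosaic), rep("false_positive", cfg$n_false_positive))
  n_sv <- length(classes)
  plan <- data.frame(id = sprintf("SV%04d", seq_len(n_sv)), class = classes,
                     stringsAsFactors = FALSE)
  plan$failure_mode <- NA_character_
  fp <- plan$class == "false_positive"
  plan$failure_mode[fp] <- rep_len(FAILURE_MODES, sum(fp))
  plan$svtype <- NA_character_
  free <- plan$class %in% c("de_novo", "inherited")
  plan$svtype[free] <- sample(names(cfg$svtype_probs), sum(free), replace = TRUE,
                              prob = cfg$svtype_probs)
  plan$svtype[plan$class == "mosaic"] <- "DEL"
  plan$svtype[fp] <- fp_svtype[plan$failure_mode[fp]]
  plan$size <- round(exp(runif(n_sv, log(cfg$sv_size_range[1]),
                               log(cfg$sv_size_range[2]))))
  plan$m <- ifelse(plan$class == "mosaic", cfg$mosaic_m, 1)
  plan$origin <- NA_character_
  poo <- plan$class %in% c("de_novo", "mosaic")
  plan$origin[poo] <- sample(c("paternal", "maternal"), sum(poo), replace = TRUE)
  plan$homology_len <- NA_integer_
  plan$homology_len[poo] <- sample(0:15, sum(poo), replace = TRUE,
                                   prob = cfg$homology_weights)

  # trio assignment: the first de novo SVs go to third-generation probands
  # so that transmission can be observed
  dn <- which(plan$class == "de_novo")
  third_gen <- sprintf("P%02d", seq_len(cfg$n_third_gen))
  n_anchor <- min(cfg$n_transmitted + 1L, length(dn), cfg$n_third_gen)
  anchor <- third_gen[seq_len(n_anchor)]
  rest <- sample(setdiff(probands, anchor), length(dn) - n_anchor)
  plan$proband <- NA_character_
  plan$proband[dn] <- c(anchor, rest)
  plan$transmitted <- FALSE
  plan$transmitted[dn[seq_len(min(cfg$n_transmitted, length(dn)))]] <- TRUE
  mos <- which(plan$class == "mosaic")
  plan$proband[mos] <- sample(setdiff(probands, plan$proband[dn]), length(mos))
  single_fp <- which(fp & plan$failure_mode != "recurrent_in_cohort")
  plan$proband[single_fp] <- sample(probands, length(single_fp), replace = TRUE)
  rec_fp <- which(fp & plan$failure_mode == "recurrent_in_cohort")
  rec_carriers <- lapply(rec_fp, function(i) sample(probands, cfg$recurrent_copies))
  plan$proband[rec_fp] <- vapply(rec_carriers, paste, character(1), collapse = ",")

  ## ---- place SVs on the genome ----------------------------------------
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  margin <- 4000L
  ord <- sample(n_sv)
  chrom_i <- 1L; cursor <- margin
  plan$chrom <- NA_character_; plan$start <- NA_integer_; plan$end <- NA_integer_
  for (k in ord) {
    repeat {
      gap <- round(runif(1, 2500, 5000))
      start <- cursor + gap
      end <- start + plan$size[k]
      if (end <= cfg$chrom_length - margin) {
        plan$chrom[k] <- chroms[chrom_i]; plan$start[k] <- start; plan$end[k] <- end
        cursor <- end
        break
      }
      chrom_i <- chrom_i + 1L; cursor <- margin
      if (chrom_i > cfg$n_chrom) {
        stop("synthetic genome too small for the requested SV load; ",
             "increase n_chrom or chrom_length")
      }
    }
  }

  ## ---- reference sequence with planted junction homology --------------
  base_codes <- c("A", "C", "G", "T")
  ref_int <- lapply(chroms, function(ch) {
    sample.int(4L, cfg$chrom_length, replace = TRUE, prob = c(.3, .2, .2, .3))
  })
  names(ref_int) <- chroms
  for (k in which(!is.na(plan$homology_len))) {
    x <- ref_int[[plan$chrom[k]]]
    h <- plan$homology_len[k]; s <- plan$start[k]; e <- plan$end[k]
    if (h > 0) x[s - seq_len(h) + 1L] <- x[e - seq_len(h) + 1L]
    if (x[s - h] == x[e - h]) x[s - h] <- (x[e - h] %% 4L) + 1L
    ref_int[[plan$chrom[k]]] <- x
  }
  gc_bins <- lapply(ref_int, function(x) {
    colMeans(matrix(x == 2L | x == 3L, nrow = cfg$bin_size))
  })
  reference <- Biostrings::DNAStringSet(vapply(ref_int, function(x) {
    paste(base_codes[x], collapse = "")
  }, character(1)))
  names(reference) <- chroms

  ## ---- genotypes -------------------------------------------------------
  n_samp <- length(samples)
  G <- matrix("hom_ref", n_sv, n_samp, dimnames = list(plan$id, samples))
  inh <- which(plan$class == "inherited")
  if (length(inh)) {
    q <- runif(length(inh), 0.05, 0.3)
    cnt <- matrix(0L, length(inh), n_samp, dimnames = list(NULL, samples))
    founders <- samples[!(samples %in% probands)]
    for (s in founders) {
      cnt[, s] <- rbinom(length(inh), 1L, q) + rbinom(length(inh), 1L, q)
    }
    for (j in seq_len(nrow(trios))) {  # trio order resolves reused probands
      p <- trios$proband[j]
      cnt[, p] <- rbinom(length(inh), 1L, cnt[, trios$sire[j]] / 2) +
                  rbinom(length(inh), 1L, cnt[, trios$dam[j]] / 2)
    }
    G[inh, ] <- c("hom_ref", "het", "hom_alt")[cnt + 1L]
  }
  for (k in dn) {
    G[k, plan$proband[k]] <- "het"
    if (plan$transmitted[k]) {
      off <- offspring_of(ped, plan$proband[k])
      G[k, off[1]] <- "het"
    }
  }
  for (k in mos) G[k, plan$proband[k]] <- "het"
  for (k in single_fp) G[k, plan$proband[k]] <- "het"
  for (i in seq_along(rec_fp)) G[rec_fp[i], rec_carriers[[i]]] <- "het"

  ## ---- per-sample depth and evidence fields ---------------------------
  depth_s <- setNames(pmax(10, round(rnorm(n_samp, cfg$mean_depth, cfg$depth_sd))),
                      samples)
  N <- n_sv * n_samp
  dn_names <- list(plan$id, samples)
  conc0 <- 200
  AB <- matrix(round(rbeta(N, 0.005 * conc0, 0.995 * conc0), 4), n_sv,
               dimnames = dn_names)
  SU <- matrix(rpois(N, cfg$noise_su_mean), n_sv, dimnames = dn_names)
  SR <- matrix(rbinom(N, as.vector(SU), 0.5), n_sv, dimnames = dn_names)
  PE <- SU - SR
  GQ <- matrix(pmin(cfg$gq_max, pmax(0, round(rnorm(N, cfg$gq_mean, cfg$gq_sd)))),
               n_sv, dimnames = dn_names)
  DHF <- matrix(round(pmax(0.01, rnorm(N, 1, cfg$fold_sd)), 4), n_sv,
                dimnames = dn_names)
  DHB <- matrix(round(pmax(0.01, rnorm(N, 1, cfg$fold_sd)), 4), n_sv,
                dimnames = dn_names)

  carrier_fold <- function(svtype, dose) {
    ifelse(svtype == "DEL", 1 - dose / 2,
           ifelse(svtype == "DUP", 1 + dose / 2, 1))
  }
  idx <- which(G == "het" | G == "hom_alt", arr.ind = TRUE)
  if (nrow(idx)) {
    mrow <- plan$m[idx[, 1]]
    dose <- ifelse(G[idx] == "het", 0.5, 1) * mrow
    ctr <- pmin(0.98, pmax(0.02, dose))
    nc <- nrow(idx)
    AB[idx] <- round(rbeta(nc, ctr * cfg$ab_concentration,
                           (1 - ctr) * cfg$ab_concentration), 4)
    SU[idx] <- rbinom(nc, depth_s[idx[, 2]], pmin(1, cfg$su_fraction * dose))
    SR[idx] <- rbinom(nc, SU[idx], 0.5)
    PE[idx] <- SU[idx] - SR[idx]
    fold <- carrier_fold(plan$svtype[idx[, 1]], dose)
    DHF[idx] <- round(pmax(0.01, rnorm(nc, fold, cfg$fold_sd)), 4)
    DHB[idx] <- round(pmax(0.01, rnorm(nc, fold, cfg$fold_sd)), 4)
  }
  # parental-evidence false positives: parents genotyped hom_ref but with
  # clear read support for the variant
  for (k in which(fp & plan$failure_mode == "parental_evidence")) {
    tr <- trios[trios$proband == plan$proband[k], ]
    for (s in c(tr$sire, tr$dam)) {
      AB[k, s] <- round(rbeta(1, 0.3 * cfg$ab_concentration,
                              0.7 * cfg$ab_concentration), 4)
      SU[k, s] <- rbinom(1, depth_s[s], 0.25) + 2L
      SR[k, s] <- rbinom(1, SU[k, s], 0.5)
      PE[k, s] <- SU[k, s] - SR[k, s]
    }
  }

  ## ---- informative SNPs inside de novo and mosaic SVs -----------------
  snvs <- sim_informative_snps(plan, ped, ref_int, depth_s, cfg$snp_spacing)

  ## ---- breakpoint read evidence ---------------------------------------
  bp_evidence <- sim_bp_evidence(plan, depth_s, cfg)

  ## ---- per-proband depth profiles -------------------------------------
  profiles <- sim_profiles(plan, G, ped, depth_s, gc_bins, cfg)

  ## ---- repeats and gene models ----------------------------------------
  rep_rows <- lapply(which(fp & plan$failure_mode == "repeat_both_breakpoints"),
                     function(k) {
    data.frame(chrom = plan$chrom[k],
               start = c(plan$start[k] - 30L, plan$end[k] - 30L),
               end = c(plan$start[k] + 30L, plan$end[k] + 30L),
               stringsAsFactors = FALSE)
  })
  bg <- data.frame(chrom = rep(chroms, each = 3),
                   start = rep(c(500L, 1200L, 2000L), cfg$n_chrom),
                   end = rep(c(650L, 1350L, 2150L), cfg$n_chrom),
                   stringsAsFactors = FALSE)
  repeats <- rbind(do.call(rbind, rep_rows), bg)
  genes <- sim_genes(plan)

  ## ---- assemble --------------------------------------------------------
  sites <- data.frame(id = plan$id, chrom = plan$chrom, start = plan$start,
                      end = plan$end, svtype = plan$svtype,
                      stringsAsFactors = FALSE)
  evidence <- data.frame(id = rep(plan$id, n_samp),
                         sample = rep(samples, each = n_sv),
                         gt = as.vector(G), gq = as.vector(GQ),
                         ab = as.vector(AB), su = as.vector(SU),
                         pe = as.vector(PE), sr = as.vector(SR),
                         dhffc = as.vector(DHF), dhbfc = as.vector(DHB),
                         stringsAsFactors = FALSE)
  cohort <- sv_cohort(sites, evidence, samples)
  truth <- plan[, c("id", "class", "failure_mode", "origin", "homology_len",
                    "m", "proband", "transmitted", "svtype", "chrom",
                    "start", "end", "size")]
  structure(list(cohort = cohort, pedigree = ped, truth = truth,
                 profiles = profiles, snvs = snvs, bp_evidence = bp_evidence,
                 repeats = repeats, genes = genes, reference = reference,
                 sample_depths = depth_s, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$truth), "planted SVs (",
      paste(names(table(x$truth$class)), table(x$truth$class),
            sep = "=", collapse = ", "),
      ") in", nrow(x$pedigree$trios), "trios\n")
  invisible(x)
}

# informative SNPs with known parental phase inside DEL/DUP de novo and
# mosaic SVs; read counts follow the copy arithmetic of the planted event
sim_informative_snps <- function(plan, ped, ref_int, depth_s, snp_spacing = 300L) {
  base_codes <- c("A", "C", "G", "T")
  rows <- list()
  for (k in which(plan$class %in% c("de_novo", "mosaic") &
                  plan$svtype %in% c("DEL", "DUP"))) {
    if (plan$end[k] - 100L < plan$start[k] + 150L) next
    pos <- seq(plan$start[k] + 150L, plan$end[k] - 100L, by = snp_spacing)
    if (!length(pos)) next
    tr <- ped$trios[ped$trios$proband == plan$proband[k], ]
    origin <- plan$origin[k]
    O <- if (origin == "paternal") tr$sire else tr$dam
    U <- if (origin == "paternal") tr$dam else tr$sire
    d <- depth_s[plan$proband[k]]
    m <- plan$m[k]
    for (p in pos) {
      refb <- base_codes[ref_int[[plan$chrom[k]]][p]]
      altb <- sample(setdiff(base_codes, refb), 1)
      mut_is_alt <- runif(1) < 0.5   # allele on the mutant haplotype
      if (plan$svtype[k] == "DEL") {
        nX <- rpois(1, d / 2)                 # retained haplotype (from U)
        nY <- rpois(1, d / 2 * (1 - m))       # deleted haplotype (from O)
        cnt_alt_p <- if (mut_is_alt) nY else nX
        cnt_ref_p <- if (mut_is_alt) nX else nY
        minor <- min(cnt_ref_p, cnt_alt_p)
        tot <- cnt_ref_p + cnt_alt_p
        gt_p <- if (tot > 0 && minor / tot > 0.1) "het"
                else if (cnt_alt_p >= cnt_ref_p) "hom_alt" else "hom_ref"
        gt_O <- if (mut_is_alt) "hom_alt" else "hom_ref"
        gt_U <- if (mut_is_alt) "hom_ref" else "hom_alt"
        cnt_O <- c(ref = if (mut_is_alt) 0 else rpois(1, depth_s[O]),
                   alt = if (mut_is_alt) rpois(1, depth_s[O]) else 0)
        cnt_U <- c(ref = if (mut_is_alt) rpois(1, depth_s[U]) else 0,
                   alt = if (mut_is_alt) 0 else rpois(1, depth_s[U]))
      } else {  # DUP: duplicated haplotype (from O) carries the excess allele
        nE <- rpois(1, d)                      # two copies
        nO <- rpois(1, d / 2)
        cnt_alt_p <- if (mut_is_alt) nE else nO
        cnt_ref_p <- if (mut_is_alt) nO else nE
        gt_p <- "het"
        gt_O <- "het"                          # origin parent het E/other
        gt_U <- if (mut_is_alt) "hom_ref" else "hom_alt"
        cnt_O <- c(ref = rpois(1, depth_s[O] / 2), alt = rpois(1, depth_s[O] / 2))
        cnt_U <- c(ref = if (mut_is_alt) rpois(1, depth_s[U]) else 0,
                   alt = if (mut_is_alt) 0 else rpois(1, depth_s[U]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = plan$chrom[k], pos = p, ref = refb, alt = altb,
        sample = c(tr$sire, tr$dam, plan$proband[k]),
        gt = c(if (origin == "paternal") gt_O else gt_U,
               if (origin == "paternal") gt_U else gt_O,
               gt_p),
        ref_reads = c(if (origin == "paternal") cnt_O["ref"] else cnt_U["ref"],
                      if (origin == "paternal") cnt_U["ref"] else cnt_O["ref"],
                      cnt_ref_p),
        alt_reads = c(if (origin == "paternal") cnt_O["alt"] else cnt_U["alt"],
                      if (origin == "paternal") cnt_U["alt"] else cnt_O["alt"],
                      cnt_alt_p),
        sv_id = plan$id[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), sample = character(0), gt = character(0),
                      ref_reads = integer(0), alt_reads = integer(0),
                      sv_id = character(0)))
  }
  do.call(rbind, rows)
}

# supporting-read evidence around both breakpoints of each planted
# non-inherited SV, shaped by the failure mode where applicable
sim_bp_evidence <- function(plan, depth_s, cfg) {
  strong_side <- function(bp, d, m = 1) {
    n <- max(rbinom(1, d, 0.5 * m), 0)
    sr <- rbinom(1, n, 0.5)
    starts <- bp - sample(10:140, n, replace = TRUE)
    list(sr = sr, pe = n - sr,
         reads = data.frame(start = starts, end = starts + 149L))
  }
  empty_side <- list(sr = 0L, pe = 0L,
                     reads = data.frame(start = integer(0), end = integer(0)))
  weak_side <- function(bp) {
    starts <- bp - c(40L, 80L)
    list(sr = 1L, pe = 1L, reads = data.frame(start = starts, end = starts + 149L))
  }
  disjoint_side <- function(bp) {
    starts <- bp + c(-400L, -200L, 50L, 250L)
    list(sr = 2L, pe = 2L, reads = data.frame(start = starts, end = starts + 100L))
  }
  out <- list()
  for (k in which(plan$class != "inherited")) {
    pb <- strsplit(plan$proband[k], ",")[[1]][1]
    d <- depth_s[pb]
    mode <- plan$failure_mode[k]
    m <- plan$m[k]
    L <- strong_side(plan$start[k], d, m)
    R <- strong_side(plan$end[k], d, m)
    if (!is.na(mode)) {
      if (mode == "one_sided_support") R <- empty_side
      if (mode == "low_read_support") { L <- weak_side(plan$start[k]); R <- weak_side(plan$end[k]) }
      if (mode == "non_overlapping_reads") L <- disjoint_side(plan$start[k])
    }
    out[[plan$id[k]]] <- list(left = L, right = R)
  }
  out
}

# binned depth profiles for every proband, consistent with its carried SVs
sim_profiles <- function(plan, G, ped, depth_s, gc_bins, cfg) {
  chroms <- names(gc_bins)
  nbins <- cfg$chrom_length %/% cfg$bin_size
  profiles <- list()
  for (pb in ped$trios$proband) {
    d <- depth_s[pb]
    per_chrom <- list()
    for (ch in chroms) {
      fold <- rep(1, nbins)
      on_ch <- which(plan$chrom == ch &
                     (G[, pb] == "het" | G[, pb] == "hom_alt") &
                     (is.na(plan$failure_mode) |
                      plan$failure_mode != "no_coverage_shift"))
      for (k in on_ch) {
        dose <- ifelse(G[k, pb] == "het", 0.5, 1) * plan$m[k]
        f <- if (plan$svtype[k] == "DEL") 1 - dose / 2
             else if (plan$svtype[k] == "DUP") 1 + dose / 2 else 1
        b <- pos_to_bin(plan$start[k] + 1L, cfg$bin_size):pos_to_bin(plan$end[k], cfg$bin_size)
        fold[b] <- f
      }
      dep <- pmax(0, round(rnorm(nbins, d * fold, sqrt(d * fold / cfg$bin_size)), 3))
      per_chrom[[ch]] <- depth_profile(dep, cfg$bin_size, ch, gc = gc_bins[[ch]])
    }
    profiles[[pb]] <- per_chrom
  }
  profiles
}

# one single-intron gene model around each de novo SV
sim_genes <- function(plan) {
  dn <- which(plan$class == "de_novo")
  if (!length(dn)) return(GenomicRanges::GRanges())
  rows <- lapply(seq_along(dn), function(i) {
    k <- dn[i]
    gid <- paste0("GENE_", plan$id[k])
    gs <- plan$start[k] - 1600L; ge <- plan$end[k] + 1600L
    strand <- if (i %% 2 == 0) "-" else "+"
    data.frame(chrom = plan$chrom[k],
               start = c(gs, gs, ge - 150L),
               end = c(ge, gs + 150L, ge),
               type = c("gene", "exon", "exon"),
               strand = strand, gene_id = gid, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand, type = df$type,
                         gene_id = df$gene_id)
}

#' Plant a junction with a controlled breakpoint-homology length
#'
#' Edits the reference so that the flanks ending at the two breakpoints of
#' `sv` share exactly `homology_len` identical terminal bases (the base one
#' position further is forced to differ), and returns the edited reference
#' together with the junction contig a split-read assembly would produce
#' (deletion: donor flank ending at `start` joined to the sequence after
#' `end`; tandem duplication: flank ending at `end` joined to the sequence
#' after `start`).
#'
#' @param reference named character vector (or `DNAStringSet`) of
#'   chromosome sequences, or a single sequence string.
#' @param sv list with `chrom`, `start`, `end`, `svtype` (`DEL` or `DUP`).
#' @param homology_len desired homology length in bp (must be shorter than
#'   `flank`).
#' @param flank junction flank length (default 20 bp).
#' @return list with `reference` (edited, as a named character vector) and
#'   `junction` (character contig of `2 * flank` bases).
#' @export
plant_junction <- function(reference, sv, homology_len, flank = 20L) {
  h <- as.integer(homology_len)
  if (h < 0 || h >= flank) {
    stop("homology_len must lie in [0, flank - 1]")
  }
  s <- chrom_string(reference, sv$chrom)
  if (sv$start - flank < 1 || sv$end + flank > nchar(s)) {
    stop("SV must leave at least 'flank' bases on both sides")
  }
  x <- strsplit(s, "")[[1]]
  st <- sv$start; en <- sv$end
  if (h > 0) x[st - seq_len(h) + 1L] <- x[en - seq_len(h) + 1L]
  if (x[st - h] == x[en - h]) {
    x[st - h] <- setdiff(c("A", "C", "G", "T"), x[en - h])[1]
  }
  s2 <- paste(x, collapse = "")
  junction <- if (identical(sv$svtype, "DUP")) {
    paste0(substr(s2, en - flank + 1L, en), substr(s2, st + 1L, st + flank))
  } else {
    paste0(substr(s2, st - flank + 1L, st), substr(s2, en + 1L, en + flank))
  }
  plain_scalar <- is.character(reference) && length(reference) == 1 &&
    is.null(names(reference))
  out_ref <- if (plain_scalar) {
    s2
  } else {
    r <- vapply(seq_along(reference), function(i) as.character(reference[[i]]),
                character(1))
    names(r) <- names(reference)
    r[[sv$chrom]] <- s2
    r
  }
  list(reference = out_ref, junction = junction)
}

#' Simulate a parent-of-origin phasing study
#'
#' Generates `n_sv` independent trios, each with one phased de novo SV
#' (deletion or duplication) containing informative SNPs, with read counts
#' either exact (`noise = "none"`) or binomially resampled at the stated
#' depth.  Used to measure parent-of-origin recovery against planted truth.
#'
#' @param n_sv number of SVs/trios.
#' @param depth per-haplotype informative read depth.
#' @param noise `"none"` (exact expected counts) or `"binomial"`.
#' @param snps_per_sv informative SNPs per SV.
#' @param prop_dup proportion of duplications (the rest are deletions).
#' @param seed RNG seed.
#' @return list with `svs` (id, coordinates, svtype, origin), `snvs`, and
#'   `trios` (sire, dam, proband per SV).
#' @export
simulate_poo_study <- function(n_sv = 100L, depth = 30, noise = c("binomial", "none"),
                               snps_per_sv = 6L, prop_dup = 0.5, seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  svs <- data.frame(id = sprintf("POO%03d", seq_len(n_sv)), chrom = "chr1",
                    start = 10000L, end = 10000L + snps_per_sv * 300L + 200L,
                    svtype = ifelse(runif(n_sv) < prop_dup, "DUP", "DEL"),
                    origin = sample(c("paternal", "maternal"), n_sv, TRUE),
                    stringsAsFactors = FALSE)
  trios <- data.frame(trio_id = svs$id, sire = paste0("S_", svs$id),
                      dam = paste0("D_", svs$id), proband = paste0("P_", svs$id),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(n_sv)) {
    pos <- svs$start[k] + 100L + 300L * (seq_len(snps_per_sv) - 1L)
    O <- if (svs$origin[k] == "paternal") trios$sire[k] else trios$dam[k]
    U <- if (svs$origin[k] == "paternal") trios$dam[k] else trios$sire[k]
    for (p in pos) {
      mut_is_alt <- runif(1) < 0.5
      if (svs$svtype[k] == "DEL") {
        tot <- round(depth)
        minor <- if (noise == "none") 0L else rbinom(1, tot, 0.01)
        cnt <- c(major = tot - minor, minor = minor)
        gt_p <- if (mut_is_alt) "hom_ref" else "hom_alt"
        gt_O <- if (mut_is_alt) "hom_alt" else "hom_ref"
        gt_U <- if (mut_is_alt) "hom_ref" else "hom_alt"
        ref_p <- if (mut_is_alt) cnt["major"] else cnt["minor"]
        alt_p <- if (mut_is_alt) cnt["minor"] else cnt["major"]
      } else {
        tot <- round(depth * 1.5)
        exc <- if (noise == "none") round(tot * 2 / 3) else rbinom(1, tot, 2 / 3)
        gt_p <- "het"
        gt_O <- "het"
        gt_U <- if (mut_is_alt) "hom_ref" else "hom_alt"
        ref_p <- if (mut_is_alt) tot - exc else exc
        alt_p <- if (mut_is_alt) exc else tot - exc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1", pos = p, ref = "A", alt = "T",
        sample = c(trios$sire[k], trios$dam[k], trios$proband[k]),
        gt = c(if (svs$origin[k] == "paternal") gt_O else gt_U,
               if (svs$origin[k] == "paternal") gt_U else gt_O,
               gt_p),
        ref_reads = c(0L, 0L, ref_p), alt_reads = c(0L, 0L, alt_p),
        sv_id = svs$id[k], stringsAsFactors = FALSE)
    }
  }
  list(svs = svs, snvs = do.call(rbind, rows), trios = trios)
}
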