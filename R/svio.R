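# Domain containers and readers/writers for the formats the pipeline touches:
# SV VCF (population genotyping dialect), PED, FASTA, BED, GFF3 and TSV.

#' Construct an SV cohort container
#'
#' Bundles the per-site records of a multi-sample SV callset with the
#' per-sample evidence produced by population SV genotyping.  Coordinates are
#' 1-based and the event size convention is `length = end - start` (the VCF
#' `POS` is the base immediately before the event, so a deletion removes
#' bases `start + 1 .. end`).  Breakend (`BND`) records carry no interval and
#' are flagged `excluded`; downstream analyses drop them.
#'
#' @param sites data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (one of `DEL`, `DUP`, `INV`, `BND`), and optionally `length`
#'   and `excluded`; `length`/`excluded` are recomputed from the convention
#'   above when absent.
#' @param evidence long data.frame with one row per site x sample:
#'   columns `id`, `sample`, `gt` (`hom_ref`/`het`/`hom_alt`/`missing`),
#'   `gq`, `ab`, `su`, `pe`, `sr`, `dhffc`, `dhbfc` (numeric, `NA` allowed).
#' @param samples character vector of sample ids in callset column order.
#' @return An object of class `sv_cohort`.
#' @export
sv_cohort <- function(sites, evidence, samples) {
  stopifnot(is.data.frame(sites), is.data.frame(evidence),
            is.character(samples), !anyDuplicated(samples))
  sites <- as.data.frame(sites)
  if (anyDuplicated(sites$id)) stop("duplicate SV ids in 'sites'")
  if (!all(sites$svtype %in% SV_TYPES)) stop("unknown svtype in 'sites'")
  bnd <- sites$svtype == "BND"
  if (is.null(sites$excluded)) sites$excluded <- bnd
  if (is.null(sites$length)) {
    sites$length <- ifelse(bnd, NA_integer_, as.integer(sites$end - sites$start))
  }
  ok <- !bnd
  if (any(ok & !(sites$end > sites$start))) {
    stop("end must exceed start for DEL/DUP/INV records")
  }
  if (any(ok & sites$length != sites$end - sites$start)) {
    stop("length must equal end - start")
  }
  miss <- setdiff(EVIDENCE_FIELDS, names(evidence))
  if (length(miss)) stop("evidence is missing fields: ", paste(miss, collapse = ", "))
  if (!all(evidence$gt %in% GT_CODES)) stop("invalid genotype code in evidence")
  if (any(!is.na(evidence$ab) & (evidence$ab < 0 | evidence$ab > 1))) {
    stop("allelic balance must lie in [0, 1]")
  }
  bad_su <- !is.na(evidence$su) & !is.na(evidence$pe) & !is.na(evidence$sr) &
    evidence$su < pmax(evidence$pe, evidence$sr)
  if (any(bad_su)) stop("su must be >= max(pe, sr)")
  if (nrow(evidence) != nrow(sites) * length(samples)) {
    stop("evidence must contain one row per site x sample")
  }
  # canonical ordering: sample-major blocks, sites in callset order
  o <- order(match(evidence$sample, samples), match(evidence$id, sites$id))
  evidence <- evidence[o, c("id", "sample", EVIDENCE_FIELDS), drop = FALSE]
  rownames(evidence) <- rownames(sites) <- NULL
  structure(list(sites = sites, evidence = evidence, samples = samples),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  tab <- table(factor(x$sites$svtype, levels = SV_TYPES))
  cat("sv_cohort:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat(" ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# site x sample matrix view of one evidence field (relies on the canonical
# ordering enforced by sv_cohort())
evidence_field <- function(cohort, field) {
  matrix(cohort$evidence[[field]],
         nrow = nrow(cohort$sites), ncol = length(cohort$samples),
         dimnames = list(cohort$sites$id, cohort$samples))
}

#' Construct a pedigree
#'
#' @param samples data.frame with columns `id`, `family`, `sire`, `dam`
#'   (`"0"` for unknown), `sex`, `phenotype`, and optionally `line` and
#'   `tissue`.
#' @return Object of class `pedigree` with `$samples`, `$trios`
#'   (`trio_id`, `sire`, `dam`, `proband`, `line`) and `$offspring`
#'   (`proband`, `offspring`): probands that appear as parents elsewhere in
#'   the pedigree yield sequenced third-generation offspring links.
#' @export
pedigree <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("id", "sire", "dam") %in% names(samples)))
  samples <- as.data.frame(samples)
  if (anyDuplicated(samples$id)) stop("duplicate sample ids in pedigree")
  if (is.null(samples$line)) samples$line <- if (is.null(samples$family)) NA else samples$family
  if (is.null(samples$tissue)) samples$tissue <- NA_character_
  known <- function(p) p != "0" & !is.na(p)
  is_trio <- known(samples$sire) & known(samples$dam)
  bad <- is_trio & !(samples$sire %in% samples$id & samples$dam %in% samples$id)
  if (any(bad)) {
    stop("trio parents absent from pedigree: ",
         paste(samples$id[bad], collapse = ", "))
  }
  trios <- data.frame(trio_id = samples$id[is_trio],
                      sire = samples$sire[is_trio],
                      dam = samples$dam[is_trio],
                      proband = samples$id[is_trio],
                      line = samples$line[is_trio],
                      stringsAsFactors = FALSE)
  off <- lapply(trios$proband, function(p) {
    samples$id[(samples$sire == p | samples$dam == p) & samples$id != p]
  })
  offspring <- data.frame(proband = rep(trios$proband, lengths(off)),
                          offspring = unlist(off, use.names = FALSE),
                          stringsAsFactors = FALSE)
  structure(list(samples = samples, trios = trios, offspring = offspring),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$samples), "samples,", nrow(x$trios), "trios,",
      nrow(x$offspring), "third-generation offspring links\n")
  invisible(x)
}

offspring_of <- function(ped, proband) {
  ped$offspring$offspring[ped$offspring$proband == proband]
}

# ---------------------------------------------------------------------------
# genotype code <-> VCF GT string

gt_to_vcf_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

# interpret a vector of diploid GT strings with respect to ALT allele `allele`;
# anything non-diploid (or containing '.') maps to "missing"
vcf_gt_decode <- function(gt, allele = 1L) {
  out <- rep("missing", length(gt))
  gt[is.na(gt)] <- "."
  parts <- strsplit(gt, "[/|]")
  n <- lengths(parts)
  ok <- n == 2L & !vapply(parts, function(p) any(p == "."), logical(1))
  cnt <- integer(length(gt))
  cnt[ok] <- vapply(parts[ok], function(p) sum(p == as.character(allele)), integer(1))
  out[ok] <- c("hom_ref", "het", "hom_alt")[cnt[ok] + 1L]
  out
}

# ---------------------------------------------------------------------------
# VCF + PED readers

#' Load a multi-sample SV callset and its pedigree
#'
#' Reads the population SV genotyping dialect (INFO `SVTYPE`/`END`, FORMAT
#' `GT:GQ:AB:SU:PE:SR:DHFFC:DHBFC`) into an [sv_cohort()] and a 6-column PED
#' file (plus optional sidecar TSV with `id`, `line`, `tissue` columns) into
#' a [pedigree()].  Records with an unrecognised `SVTYPE` are kept with type
#' `BND` and flagged excluded.  Multi-allelic sites are split into one record
#' per ALT allele.  Absent FORMAT keys yield missing (`NA`) evidence, which
#' conservatively fails any filter that needs them.
#'
#' @param sv_vcf path to the SV VCF.
#' @param ped path to the PED file.
#' @param meta optional path to a TSV with columns `id`, `line`, `tissue`.
#' @return `list(cohort = sv_cohort, pedigree = pedigree)`.
#' @export
load_cohort <- function(sv_vcf, ped, meta = NULL) {
  pedi <- read_pedigree(ped, meta)
  v <- vcfR::read.vcfR(sv_vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  absent <- setdiff(unique(c(pedi$trios$sire, pedi$trios$dam, pedi$trios$proband)),
                    samples)
  if (length(absent)) {
    stop("trio member(s) absent from the VCF: ", paste(absent, collapse = ", "))
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svtype[is.na(svtype) | !svtype %in% SV_TYPES] <- "BND"
  end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("sv", which(is.na(ids) | ids == "."))
  n_alt <- vapply(strsplit(fix[, "ALT"], ","), length, integer(1))
  n_alt[is.na(fix[, "ALT"])] <- 1L

  gt_raw <- vcfR::extract.gt(v, "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, samples))
  num_field <- function(key) {
    m <- tryCatch(vcfR::extract.gt(v, key, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) return(matrix(NA_real_, nrow(gt_raw), ncol(gt_raw)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m
  }
  fields <- lapply(c(gq = "GQ", ab = "AB", su = "SU", pe = "PE", sr = "SR",
                     dhffc = "DHFFC", dhbfc = "DHBFC"), num_field)

  row_i <- rep(seq_along(pos), n_alt)
  allele <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  out_id <- ifelse(n_alt[row_i] > 1L,
                   paste0(ids[row_i], "_", allele), ids[row_i])
  bnd <- svtype[row_i] == "BND"
  sites <- data.frame(id = out_id,
                      chrom = fix[row_i, "CHROM"],
                      start = pos[row_i],
                      end = ifelse(bnd, NA_integer_, end[row_i]),
                      svtype = svtype[row_i],
                      stringsAsFactors = FALSE)
  sites$length <- ifelse(bnd, NA_integer_, sites$end - sites$start)
  sites$excluded <- bnd

  gt_long <- unlist(lapply(samples, function(s) {
    vapply(seq_along(row_i), function(k) {
      vcf_gt_decode(gt_raw[row_i[k], s], allele[k])
    }, character(1))
  }), use.names = FALSE)
  evidence <- data.frame(id = rep(sites$id, times = length(samples)),
                         sample = rep(samples, each = nrow(sites)),
                         gt = gt_long, stringsAsFactors = FALSE)
  for (f in names(fields)) {
    evidence[[f]] <- as.vector(fields[[f]][row_i, , drop = FALSE])
  }
  list(cohort = sv_cohort(sites, evidence, samples), pedigree = pedi)
}

#' Read a PED file (optionally with a line/tissue sidecar TSV)
#' @inheritParams load_cohort
#' @return A [pedigree()].
#' @export
read_pedigree <- function(ped, meta = NULL) {
  tab <- read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("family", "id", "sire", "dam", "sex", "phenotype"))
  tab$sire <- as.character(tab$sire)
  tab$dam <- as.character(tab$dam)
  tab$line <- tab$family
  if (!is.null(meta)) {
    m <- read.delim(meta, stringsAsFactors = FALSE)
    idx <- match(tab$id, m$id)
    if ("line" %in% names(m)) tab$line <- m$line[idx]
    if ("tissue" %in% names(m)) tab$tissue <- m$tissue[idx]
  }
  pedigree(tab)
}

#' Write a pedigree as PED (+ sidecar TSV with line/tissue labels)
#' @param ped A [pedigree()].
#' @param path output PED path.
#' @param meta_path optional sidecar TSV path.
#' @export
write_pedigree <- function(ped, path, meta_path = NULL) {
  s <- ped$samples
  sex <- if (is.null(s$sex)) 0L else s$sex
  phe <- if (is.null(s$phenotype)) 0L else s$phenotype
  write.table(data.frame(s$family, s$id, s$sire, s$dam, sex, phe),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(meta_path)) {
    write.table(data.frame(id = s$id, line = s$line, tissue = s$tissue),
                meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF writer (the same dialect load_cohort() reads)

fmt_num <- function(x, digits = 15) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = digits))
}

#' Write an SV cohort as a VCF 4.2 file
#'
#' Emits the dialect [load_cohort()] reads; numeric evidence survives a
#' write/load round trip bit-exactly when values carry at most 15
#' significant digits.
#'
#' @param cohort An [sv_cohort()].
#' @param path output VCF path.
#' @param info optional named character vector (by site id) of extra INFO
#'   payload appended verbatim, e.g. filter-trace tags.
#' @export
write_cohort_vcf <- function(cohort, path, info = NULL) {
  s <- cohort$sites
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT\">",
    "##INFO=<ID=DNSV,Number=1,Type=String,Description=\"de novo filter trace summary\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allelic balance: alt reads / (ref + alt reads)\">",
    "##FORMAT=<ID=SU,Number=1,Type=Integer,Description=\"Total supporting reads\">",
    "##FORMAT=<ID=PE,Number=1,Type=Integer,Description=\"Discordant paired-end reads\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
    "##FORMAT=<ID=DHFFC,Number=1,Type=Float,Description=\"duphold flank fold-change\">",
    "##FORMAT=<ID=DHBFC,Number=1,Type=Float,Description=\"duphold GC-matched bin fold-change\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(cohort$samples, collapse = "\t")))
  inf <- paste0("SVTYPE=", s$svtype)
  has_iv <- s$svtype != "BND"
  inf[has_iv] <- paste0(inf[has_iv], ";END=", s$end[has_iv], ";SVLEN=",
                        ifelse(s$svtype[has_iv] == "DEL", -s$length[has_iv],
                               s$length[has_iv]))
  if (!is.null(info)) {
    extra <- info[s$id]
    add <- !is.na(extra)
    inf[add] <- paste0(inf[add], ";", extra[add])
  }
  mats <- lapply(EVIDENCE_FIELDS, function(f) evidence_field(cohort, f))
  names(mats) <- EVIDENCE_FIELDS
  cell <- matrix(gt_to_vcf_code[mats$gt], nrow = nrow(s))
  for (f in c("gq", "ab", "su", "pe", "sr", "dhffc", "dhbfc")) {
    cell <- matrix(paste(cell, fmt_num(mats[[f]]), sep = ":"), nrow = nrow(s))
  }
  body <- paste(s$chrom, s$start, s$id, "N", paste0("<", s$svtype, ">"),
                ".", ".", inf, "GT:GQ:AB:SU:PE:SR:DHFFC:DHBFC",
                apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write cohort VCF + PED together
#' @inheritParams write_cohort_vcf
#' @param ped A [pedigree()].
#' @param ped_path,meta_path output paths for the PED file and its sidecar.
#' @export
write_cohort <- function(cohort, path, ped, ped_path, meta_path = NULL) {
  write_cohort_vcf(cohort, path)
  write_pedigree(ped, ped_path, meta_path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# annotation readers

#' Read repeat intervals from a BED file
#'
#' BED is 0-based half-open; the result is 1-based closed coordinates.
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_repeats <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read gene models (gene + exon features) from a GFF3 file
#'
#' @param path GFF3 path.
#' @return `GRanges` restricted to `gene` and `exon` features with a
#'   `gene_id` metadata column.
#' @export
read_gene_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                 error = function(e) stop("malformed GFF3: ", conditionMessage(e)))
  gr <- gr[gr$type %in% c("gene", "exon")]
  gid <- as.character(gr$ID)
  if (!is.null(gr$Parent)) {
    par <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    gid[!is.na(par)] <- par[!is.na(par)]   # exons point at their gene
  }
  gr$gene_id <- sub("^gene:", "", gid)
  gr
}

# ---------------------------------------------------------------------------
# result writers

#' Write pipeline result files
#'
#' Emits, under `out_dir`: `confirmed.tsv` (one row per confirmed dnSV with
#' type, position, size, parent of origin, locus, mechanism, cluster,
#' zygosity and transmission status), `candidates.vcf` (candidate sites with
#' their filter-trace summary in INFO, when the cohort is supplied),
#' `rejections.tsv` (one row per failed filter check) and `rate.json`.
#'
#' @param candidates candidate table from [filter_cascade()] (or `NULL`).
#' @param characterisations confirmed-dnSV characterisation table
#'   (possibly zero rows).
#' @param out_dir output directory, created if needed.
#' @param rate optional [estimate_rate()] result.
#' @param cohort optional [sv_cohort()] backing the candidate VCF.
#' @param trace optional long filter trace from [filter_cascade()].
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(candidates, characterisations, out_dir,
                          rate = NULL, cohort = NULL, trace = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) stop("cannot write to ", out_dir)
  cols <- c("id", "svtype", "chrom", "start", "end", "size",
            "parent_of_origin", "locus", "genic_context", "intron",
            "mechanism", "homology_len", "cluster", "zygosity", "transmission")
  ch <- characterisations
  if (is.null(ch) || nrow(ch) == 0) {
    ch <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    for (cc in setdiff(cols, names(ch))) ch[[cc]] <- NA
    ch <- ch[, cols]
  }
  write.table(ch, file.path(out_dir, "confirmed.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort) && !is.null(candidates) && nrow(candidates)) {
    idx <- match(unique(candidates$id), cohort$sites$id)
    sub <- subset_cohort(cohort, cohort$sites$id[idx])
    stat <- vapply(sub$sites$id, function(i) {
      rows <- candidates[candidates$id == i, ]
      paste0("DNSV=", paste(paste0(rows$trio_id, ":", rows$status), collapse = "|"))
    }, character(1))
    write_cohort_vcf(sub, file.path(out_dir, "candidates.vcf"), info = stat)
  }
  if (!is.null(trace)) {
    write.table(trace, file.path(out_dir, "rejections.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  r <- if (is.null(rate)) {
    list(k = nrow(ch), n = NA, rate = if (nrow(ch)) NA else 0)
  } else {
    unclass(rate)
  }
  jsonlite::write_json(r, file.path(out_dir, "rate.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read back a confirmed-dnSV TSV written by [write_results()]
#' @param path TSV path.
#' @export
read_results_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(id = "character", chrom = "character"))
}

# subset a cohort to a set of site ids (keeps all samples)
subset_cohort <- function(cohort, ids) {
  keep_s <- cohort$sites$id %in% ids
  keep_e <- cohort$evidence$id %in% ids
  sv_cohort(cohort$sites[keep_s, , drop = FALSE],
            cohort$evidence[keep_e, , drop = FALSE],
            cohort$samples)
}
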