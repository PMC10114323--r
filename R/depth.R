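# Binned read-depth profiles and duphold-style depth fold-changes.

#' Construct a binned depth profile for one chromosome
#'
#' @param depth numeric vector of non-negative per-bin read depth; bins tile
#'   the sequence without overlap, bin `i` covering positions
#'   `(i-1)*bin_size + 1 .. i*bin_size`.
#' @param bin_size bin width in bp (1 allowed).
#' @param chrom chromosome name.
#' @param gc optional per-bin GC fraction in `[0, 1]` (required for
#'   [compute_dhbfc()]).
#' @export
depth_profile <- function(depth, bin_size = 1L, chrom = "chr1", gc = NULL) {
  stopifnot(is.numeric(depth), all(depth >= 0, na.rm = TRUE), bin_size >= 1)
  if (!is.null(gc)) {
    stopifnot(length(gc) == length(depth), all(gc >= 0 & gc <= 1, na.rm = TRUE))
  }
  structure(list(depth = as.numeric(depth), bin_size = as.integer(bin_size),
                 chrom = chrom, gc = gc),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile:", x$chrom, "-", length(x$depth), "bins of",
      x$bin_size, "bp; median depth", stats::median(x$depth), "\n")
  invisible(x)
}

profile_length <- function(profile) length(profile$depth) * profile$bin_size

pos_to_bin <- function(pos, bin_size) (as.integer(pos) - 1L) %/% bin_size + 1L

bins_in <- function(profile, from, to) {
  pos_to_bin(from, profile$bin_size):pos_to_bin(to, profile$bin_size)
}

#' Depth flank fold-change (DHFFC)
#'
#' Ratio of the median depth inside an SV interval to the median depth of the
#' 1,000 bp flanks on either side, the duphold flank fold-change.  The SV
#' occupies bases `start + 1 .. end` (`POS` is the base before the event).
#' Heterozygous deletions depress the value below 1.
#'
#' @param profile a [depth_profile()].
#' @param start,end SV coordinates (1-based, `length = end - start`).
#' @param flank_bp flank width in bp on each side (default 1000).
#' @return Positive number; `Inf` when the flank median is 0.
#' @export
compute_dhffc <- function(profile, start, end, flank_bp = 1000L) {
  stopifnot(end > start)
  if (start - flank_bp < 0 || end + flank_bp > profile_length(profile)) {
    stop("SV interval plus flanks must lie inside the depth profile")
  }
  inside <- profile$depth[bins_in(profile, start + 1L, end)]
  flank <- profile$depth[c(bins_in(profile, start - flank_bp + 1L, start),
                           bins_in(profile, end + 1L, end + flank_bp))]
  mf <- stats::median(flank)
  if (mf == 0) return(Inf)
  stats::median(inside) / mf
}

#' Depth GC-matched bin fold-change (DHBFC)
#'
#' Ratio of the median depth inside an SV interval to the median depth of all
#' other profile bins whose GC fraction falls in the same GC stratum
#' (strata are `gc_width`-wide bins of GC fraction), the duphold bin
#' fold-change.  Duplications elevate the value above 1.  When no bin
#' outside the interval matches the stratum the genome-wide median is used
#' and the result carries attribute `gc_fallback = TRUE`.
#'
#' @inheritParams compute_dhffc
#' @param gc_width GC stratum width (default 0.05).
#' @export
compute_dhbfc <- function(profile, start, end, gc_width = 0.05) {
  stopifnot(end > start)
  if (is.null(profile$gc)) stop("profile carries no GC track")
  if (start < 0 || end > profile_length(profile)) {
    stop("SV interval must lie inside the depth profile")
  }
  idx <- bins_in(profile, start + 1L, end)
  stratum <- function(g) pmin(floor(g / gc_width), floor(1 / gc_width) - 1)
  s_iv <- stratum(mean(profile$gc[idx]))
  pool <- setdiff(which(stratum(profile$gc) == s_iv), idx)
  fallback <- length(pool) == 0
  ref <- if (fallback) stats::median(profile$depth[-idx]) else stats::median(profile$depth[pool])
  if (ref == 0) return(structure(Inf, gc_fallback = fallback))
  structure(stats::median(profile$depth[idx]) / ref, gc_fallback = fallback)
}

#' Per-breakpoint coverage step of an SV
#'
#' For each breakpoint, the ratio of the median depth over `window` bp on the
#' SV-interior side to the median depth over `window` bp on the exterior
#' side.  A real heterozygous deletion shows a step below 1 at both
#' breakpoints; a duplication a step above 1.  Used by the evidence-review
#' rule that demands a coverage shift at the breakpoints.
#'
#' @inheritParams compute_dhffc
#' @param window window width in bp (default 500).
#' @return Named numeric vector `c(left =, right =)`; `NA` where a window
#'   falls outside the profile.
#' @export
breakpoint_steps <- function(profile, start, end, window = 500L) {
  med <- function(from, to) {
    if (from < 1 || to > profile_length(profile)) return(NA_real_)
    stats::median(profile$depth[bins_in(profile, from, to)])
  }
  w <- as.integer(window)
  left <- med(start + 1L, min(start + w, end)) / med(start - w + 1L, start)
  right <- med(max(end - w + 1L, start + 1L), end) / med(end + 1L, end + w)
  c(left = left, right = right)
}
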