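# Locating anticodon position 34 on the sequenced strand and quantifying
# the T:C signal there.
#
# The sequenced strand is the reverse complement of the tRNA (cDNA), so the
# three called bases covering the anticodon read as the DNA form of the
# targeted codon, and tRNA position 34 -- the 5'-most anticodon base --
# corresponds to the LAST base of that triplet in sequencing order.
# Reverse transcriptase reads inosine as guanosine and incorporates C;
# unmodified adenosine templates only T. The C share of the T+C signal at
# that position therefore estimates the inosine-modified fraction.

#' Locate the anticodon triplet in a chromatogram
#'
#' Finds, in the called bases, the position of the sequenced anticodon
#' triplet using the flanking reference context: first by exact match of
#' `flank` bases on each side (the triplet itself is a wildcard, since a
#' mixed position may be miscalled), then -- if no exact match exists -- by
#' minimizing the total edit distance of the two flanks over all candidate
#' placements. Ambiguous placements (two or more equally good) and
#' placements above the edit-distance cap are errors.
#'
#' @param chrom A [chromatogram()].
#' @param reference_cdna Reference cDNA sequence (DNA alphabet) with the
#'   anticodon triplet marked: either the unique run of 3 lowercase bases in
#'   an otherwise uppercase string (as produced by [reference_cdna()]), or
#'   any string plus an explicit `triplet_start`.
#' @param flank Number of context bases used on each side (default 12);
#'   the reference must provide at least this much context.
#' @param triplet_start Optional explicit 1-based start of the triplet in
#'   `reference_cdna`, overriding lowercase marking.
#' @param max_edit Maximum total flank edit distance tolerated by the
#'   alignment fallback (default 3).
#' @return Object of class `trace_locus`: `trace_index` (index into
#'   `peak_locations` for the base complementary to tRNA position 34, i.e.
#'   the third triplet base), `anticodon_window` (the three indices) and
#'   `orientation` (`"reverse_complement"`).
#' @export
locate_anticodon <- function(chrom, reference_cdna, flank = 12L,
                             triplet_start = NULL, max_edit = 3L) {
  stopifnot(inherits(chrom, "chromatogram"))
  ref <- as.character(reference_cdna)
  if (is.null(triplet_start)) {
    m <- gregexpr("[acgt]{3}", ref)[[1]]
    runs <- m[m > 0 & attr(m, "match.length") == 3L]
    if (length(runs) != 1L) {
      stop(paste("reference must mark the anticodon triplet as a unique",
                 "3-base lowercase run, or triplet_start must be given"),
           call. = FALSE)
    }
    triplet_start <- runs[1]
  }
  ref <- toupper(ref)
  if (triplet_start - flank < 1L ||
      triplet_start + 2L + flank > nchar(ref)) {
    stop(sprintf("reference provides fewer than %d context bases on a side",
                 flank), call. = FALSE)
  }
  left <- substr(ref, triplet_start - flank, triplet_start - 1L)
  right <- substr(ref, triplet_start + 3L, triplet_start + 2L + flank)
  called <- chrom$called_bases
  n <- nchar(called)

  # exact match: both flanks, wildcard triplet
  pat <- paste0(left, "[ACGTN]{3}", right)
  hits <- gregexpr(pat, called)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) > 1L) {
    stop("anticodon context found more than once in the trace",
         call. = FALSE)
  }
  if (length(hits) == 1L) {
    start <- hits[1] + flank
  } else {
    # alignment fallback: minimize summed flank edit distance
    cand <- (flank + 1L):(n - 2L - flank)
    if (length(cand) == 0L || cand[1] > cand[length(cand)]) {
      stop("trace too short to contain the anticodon context",
           call. = FALSE)
    }
    scores <- vapply(cand, function(p) {
      dl <- utils::adist(left, substr(called, p - flank, p - 1L))
      dr <- utils::adist(right, substr(called, p + 3L, p + 2L + flank))
      as.numeric(dl + dr)
    }, numeric(1))
    best <- min(scores)
    if (best > max_edit) {
      stop(sprintf(paste("anticodon context not found: best flank edit",
                         "distance %d exceeds cap %d"), best, max_edit),
           call. = FALSE)
    }
    at <- cand[scores == best]
    if (length(at) > 1L) {
      stop("anticodon context matches ambiguously in the trace",
           call. = FALSE)
    }
    start <- at
  }
  window <- start:(start + 2L)
  structure(
    list(trace_index = window[3L], anticodon_window = window,
         orientation = "reverse_complement"),
    class = "trace_locus"
  )
}

#' Baseline-subtracted peak areas at a called-base position
#'
#' Integrates each channel by the trapezoidal rule over a window centered on
#' the peak location, extending half the local inter-peak spacing to each
#' side. Before integration, a per-channel baseline is subtracted per
#' sample and negative samples are clamped to zero. The baseline of a
#' channel is a quantile (default 0.5, the median) of its signal taken over
#' samples at least one typical peak spacing away from any called peak of
#' that same base, so peaks do not contaminate their own baseline estimate;
#' when too few samples remain the whole channel is used. The median is
#' used rather than a low percentile because, over baseline-dominated
#' samples, it tracks the true baseline level both on noise-free traces and
#' under noise, whereas a low order statistic of a noisy baseline sits
#' about 1.6 noise sd below it, inflating every peak area and biasing small
#' mixed-base fractions upward. A window that would extend beyond the
#' trace is truncated with a warning.
#'
#' @param chrom A `chromatogram`.
#' @param trace_index Index into `peak_locations` of the base to quantify
#'   (typically `trace_locus$trace_index`).
#' @param baseline_quantile Quantile of each channel used as its baseline,
#'   default 0.5 (the median).
#' @return Object of class `peak_areas`: `areas` (named numeric, one per
#'   base, >= 0), `window` (sample bounds used) and `baseline` (per-channel
#'   subtracted level).
#' @export
integrate_peak <- function(chrom, trace_index, baseline_quantile = 0.5) {
  stopifnot(is.numeric(baseline_quantile), length(baseline_quantile) == 1L,
            baseline_quantile >= 0, baseline_quantile <= 1)
  stopifnot(inherits(chrom, "chromatogram"))
  ploc <- chrom$peak_locations
  k <- length(ploc)
  trace_index <- as.integer(trace_index)
  if (length(trace_index) != 1L || trace_index < 1L || trace_index > k) {
    stop("trace_index out of range", call. = FALSE)
  }
  center <- ploc[trace_index]
  spacing_of <- function(i, j) (ploc[j] - ploc[i]) / 2
  half_left <- if (trace_index > 1L) spacing_of(trace_index - 1L, trace_index)
               else if (k > 1L) spacing_of(trace_index, trace_index + 1L)
               else 6
  half_right <- if (trace_index < k) spacing_of(trace_index, trace_index + 1L)
                else if (k > 1L) spacing_of(trace_index - 1L, trace_index)
                else 6
  len <- length(chrom$channels$A)
  lo_raw <- center - half_left
  hi_raw <- center + half_right
  lo <- max(1L, as.integer(ceiling(lo_raw)))
  hi <- min(len, as.integer(floor(hi_raw)))
  if (lo_raw < 1 || hi_raw > len) {
    warning("integration window extends beyond the trace; truncated")
  }
  spacing <- if (k > 1L) stats::median(diff(ploc)) else 12
  called <- strsplit(chrom$called_bases, "")[[1]]
  baseline <- vapply(DNA_BASES, function(b) {
    near_peak <- rep(FALSE, len)
    for (p in ploc[called == b]) {
      near_peak[max(1L, p - spacing):min(len, p + spacing)] <- TRUE
    }
    keep <- which(!near_peak)
    if (length(keep) < max(10L, len %/% 4L)) keep <- seq_len(len)
    stats::quantile(chrom$channels[[b]][keep], probs = baseline_quantile,
                    names = FALSE)
  }, numeric(1))
  areas <- vapply(DNA_BASES, function(b) {
    y <- pmax(chrom$channels[[b]][lo:hi] - baseline[[b]], 0)
    if (length(y) < 2L) return(sum(y))
    sum(y) - (y[1] + y[length(y)]) / 2 # trapezoid, unit sample spacing
  }, numeric(1))
  structure(
    list(areas = areas, window = c(lo, hi),
         baseline = stats::setNames(baseline, DNA_BASES)),
    class = "peak_areas"
  )
}

#' Estimate the inosine-modified fraction from peak areas
#'
#' Inosine templates C and unmodified adenosine templates T during reverse
#' transcription, so the modified fraction is estimated as the C share of
#' the T+C signal at the position pairing tRNA base 34:
#' `area_C / (area_C + area_T)`. The A and G channels are ignored by the
#' estimator but remain available in the `peak_areas` object.
#'
#' @param areas A `peak_areas` object from [integrate_peak()].
#' @return Estimated modified fraction in \[0, 1\].
#' @export
estimate_inosine_fraction <- function(areas) {
  if (!inherits(areas, "peak_areas")) {
    stop("areas must be a peak_areas object", call. = FALSE)
  }
  tc <- areas$areas[["T"]] + areas$areas[["C"]]
  if (tc <= 0) {
    stop("no T or C signal at the quantified position", call. = FALSE)
  }
  unname(areas$areas[["C"]] / tc)
}

#' Call inosine modification from an estimated fraction
#'
#' Two gates must both pass: an absolute visibility threshold (default 5%,
#' the level clearly evident above chromatogram baselines) and a 3-sigma
#' gate against the trace's own baseline noise, so that noisy baselines are
#' never called modified ("indistinguishable from baseline").
#'
#' @param fraction Estimated modified fraction in \[0, 1\].
#' @param baseline_noise_mean,baseline_noise_sd Mean and sd of the fraction
#'   estimator at known-unmodified positions of the same trace (same scale
#'   as `fraction`); see [trace_noise_stats()].
#' @param threshold Absolute modification threshold, default 0.05.
#' @return Object of class `inosine_call`: `fraction`,
#'   `baseline_noise_mean`, `baseline_noise_sd`, `threshold`, `modified`.
#' @export
call_modification <- function(fraction, baseline_noise_mean,
                              baseline_noise_sd, threshold = 0.05) {
  vals <- c(fraction, baseline_noise_mean, baseline_noise_sd, threshold)
  if (!all(is.finite(vals)) || any(vals < 0) || fraction > 1) {
    stop("inputs must be fractions in [0, 1] (sd >= 0)", call. = FALSE)
  }
  modified <- fraction >= threshold &&
    fraction >= baseline_noise_mean + 3 * baseline_noise_sd
  structure(
    list(fraction = fraction,
         baseline_noise_mean = baseline_noise_mean,
         baseline_noise_sd = baseline_noise_sd,
         threshold = threshold,
         modified = modified),
    class = "inosine_call"
  )
}

#' @export
print.inosine_call <- function(x, ...) {
  cat(sprintf("inosine fraction %.3f (baseline %.3f ± %.3f): %s\n",
              x$fraction, x$baseline_noise_mean, x$baseline_noise_sd,
              if (x$modified) "MODIFIED" else "not modified"))
  invisible(x)
}

#' Baseline noise of the fraction estimator on a trace
#'
#' Runs the C/(C+T) estimator at every called T peak except the excluded
#' indices (normally the anticodon window) and returns the mean and sd of
#' those fractions. Since a pure-T position has a true modified fraction of
#' zero, this measures the estimator's noise floor on the trace at hand --
#' residual baseline, cross-channel bleed, and integration error included.
#'
#' @param chrom A `chromatogram`.
#' @param exclude Integer indices into `peak_locations` to skip.
#' @return List with `mean`, `sd` (0 when fewer than 2 usable positions)
#'   and `n`.
#' @export
trace_noise_stats <- function(chrom, exclude = integer()) {
  stopifnot(inherits(chrom, "chromatogram"))
  bases <- strsplit(chrom$called_bases, "")[[1]]
  idx <- setdiff(which(bases == "T"), as.integer(exclude))
  if (length(idx) == 0L) {
    stop("no unexcluded T positions available for noise estimation",
         call. = FALSE)
  }
  fr <- vapply(idx, function(i) {
    estimate_inosine_fraction(integrate_peak(chrom, i))
  }, numeric(1))
  list(mean = mean(fr),
       sd = if (length(fr) > 1L) stats::sd(fr) else 0,
       n = length(fr))
}
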