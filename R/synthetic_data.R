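# Synthetic chromatograms, synthetic screen replicates, and the packaged
# reassignment-efficiency fixture, so every pipeline stage runs without
# external data.

#' Specification for a synthetic chromatogram
#'
#' Each base of `sequence` contributes one Gaussian peak to its channel;
#' at mixed positions the peak amplitude is split across bases according to
#' the given fractions (emulating, e.g., a partially inosine-modified
#' template that reads as a T/C mixture). A constant baseline and Gaussian
#' noise are added to all channels. Default morphology (12-sample peak
#' spacing, sigma 2.5, amplitude 1000, baseline 20, noise sd 10) mimics a
#' typical analyzed capillary trace; all parameters are overridable.
#'
#' @param sequence DNA string to simulate.
#' @param mixed_positions Named list: names are 1-based base indices (as
#'   character), values are named fraction vectors summing to 1, e.g.
#'   `list("15" = c(T = 0.85, C = 0.15))`.
#' @param peak_spacing Samples between successive peak centers.
#' @param peak_sigma Gaussian peak width in samples (< `peak_spacing`).
#' @param amplitude Peak amplitude in signal units.
#' @param baseline_level Constant baseline added to every channel.
#' @param noise_sd Gaussian noise sd in signal units (0 = noise-free).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Object of class `trace_spec`.
#' @export
trace_spec <- function(sequence, mixed_positions = list(),
                       peak_spacing = 12, peak_sigma = 2.5,
                       amplitude = 1000, baseline_level = 20,
                       noise_sd = 10, seed = NULL) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("sequence must be a DNA string over A, C, G, T", call. = FALSE)
  }
  stopifnot(peak_spacing > 0, peak_sigma > 0, amplitude > 0,
            baseline_level >= 0, noise_sd >= 0)
  if (peak_sigma >= peak_spacing) {
    stop("peak_sigma must be smaller than peak_spacing", call. = FALSE)
  }
  n <- nchar(sequence)
  for (key in names(mixed_positions)) {
    i <- suppressWarnings(as.integer(key))
    fr <- mixed_positions[[key]]
    if (is.na(i) || i < 1L || i > n) {
      stop(sprintf("mixed position '%s' outside the sequence", key),
           call. = FALSE)
    }
    if (is.null(names(fr)) || !all(names(fr) %in% DNA_BASES) ||
        any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
      stop(sprintf("fractions at position %s must be named by base and sum to 1",
                   key), call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence, mixed_positions = mixed_positions,
         peak_spacing = peak_spacing, peak_sigma = peak_sigma,
         amplitude = amplitude, baseline_level = baseline_level,
         noise_sd = noise_sd, seed = seed),
    class = "trace_spec"
  )
}

#' Simulate a chromatogram from a trace specification
#'
#' Peak centers sit at `i * peak_spacing` for base `i` (one spacing of lead
#' margin on each end); called bases are the majority base at each position
#' (ties broken in A, C, G, T order); peak locations are the exact centers.
#' Output is deterministic given the spec's seed.
#'
#' @param spec A [trace_spec()].
#' @return A [chromatogram()].
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  bases <- strsplit(spec$sequence, "")[[1]]
  n <- length(bases)
  centers <- round(spec$peak_spacing * seq_len(n))
  len <- as.integer(round(spec$peak_spacing * (n + 1)))
  x <- seq_len(len)
  channels <- stats::setNames(
    lapply(DNA_BASES, function(b) numeric(len)), DNA_BASES)
  called <- character(n)
  for (i in seq_len(n)) {
    key <- as.character(i)
    fr <- if (key %in% names(spec$mixed_positions)) {
      spec$mixed_positions[[key]]
    } else {
      stats::setNames(1, bases[i])
    }
    shape <- exp(-(x - centers[i])^2 / (2 * spec$peak_sigma^2))
    for (b in names(fr)) {
      if (fr[[b]] > 0) {
        channels[[b]] <- channels[[b]] + spec$amplitude * fr[[b]] * shape
      }
    }
    ord <- match(names(fr), DNA_BASES)
    called[i] <- names(fr)[order(-fr, ord)][1]
  }
  for (b in DNA_BASES) {
    noise <- if (spec$noise_sd > 0) stats::rnorm(len, 0, spec$noise_sd)
             else 0
    channels[[b]] <- pmax(channels[[b]] + spec$baseline_level + noise, 0)
  }
  chromatogram(channels, centers, paste(called, collapse = ""))
}

#' Specification for synthetic screen replicates
#'
#' Raw per-replicate fluorescence values are drawn around a true
#' reassignment efficiency placed between the 0% and 100% reference
#' anchors: `ref0 + (true_re/100) * (ref100 - ref0) + noise`, with the
#' per-replicate noise sd expressed in percent of the reference range.
#' Reference wells are emitted alongside under the same noise model.
#' Defaults (n = 12 replicates, 0.5% per-replicate sd) reflect a
#' well-behaved plate-reader screen whose reported efficiencies carry
#' standard deviations of a few tenths of a percent.
#'
#' @param true_re True reassignment efficiency in percent.
#' @param n_replicates Number of biological replicates (>= 1), default 12.
#' @param replicate_sd Per-replicate noise sd in percent, default 0.5.
#' @param ref0_value,ref100_value Reference fluorescence values in arbitrary
#'   units (`ref100_value > ref0_value`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Object of class `screen_spec`.
#' @export
screen_spec <- function(true_re, n_replicates = 12L, replicate_sd = 0.5,
                        ref0_value = 150, ref100_value = 25150,
                        seed = NULL) {
  stopifnot(is.numeric(true_re), length(true_re) == 1L,
            n_replicates >= 1L, replicate_sd >= 0,
            ref100_value > ref0_value)
  structure(
    list(true_re = true_re, n_replicates = as.integer(n_replicates),
         replicate_sd = replicate_sd, ref0_value = ref0_value,
         ref100_value = ref100_value, seed = seed),
    class = "screen_spec"
  )
}

#' Simulate raw screen measurements
#'
#' @param spec A [screen_spec()].
#' @param anticodon,codon Labels attached to the sample rows (optional,
#'   useful when concatenating several simulated systems).
#' @return Data.frame of raw measurements with columns `replicate_id`,
#'   `construct` (`sample`/`ref0`/`ref100`), `anticodon`, `codon`, `value`,
#'   `batch`; deterministic given the spec's seed.
#' @export
simulate_screen <- function(spec, anticodon = NA_character_,
                            codon = NA_character_) {
  stopifnot(inherits(spec, "screen_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rng <- spec$ref100_value - spec$ref0_value
  sd_raw <- spec$replicate_sd / 100 * rng
  nr <- spec$n_replicates
  noise <- function() if (sd_raw > 0) stats::rnorm(nr, 0, sd_raw) else 0
  true_raw <- spec$ref0_value + spec$true_re / 100 * rng
  rows <- rbind(
    data.frame(replicate_id = seq_len(nr), construct = "sample",
               anticodon = anticodon, codon = codon,
               value = true_raw + noise(), stringsAsFactors = FALSE),
    data.frame(replicate_id = seq_len(nr), construct = "ref0",
               anticodon = NA_character_, codon = NA_character_,
               value = spec$ref0_value + noise(), stringsAsFactors = FALSE),
    data.frame(replicate_id = seq_len(nr), construct = "ref100",
               anticodon = NA_character_, codon = NA_character_,
               value = spec$ref100_value + noise(), stringsAsFactors = FALSE)
  )
  rows$value <- pmax(rows$value, 0)
  rows$batch <- "all"
  rows
}

# -- packaged reassignment-efficiency fixture ------------------------------

.fixture_path <- function() {
  system.file("extdata", "reassignment_efficiencies.tsv",
              package = "wobbleA34", mustWork = TRUE)
}

#' The packaged 15-anticodon reassignment-efficiency fixture
#'
#' Per-anticodon reassignment efficiencies (mean, sd) of the orthogonal
#' tyrosine tRNA at the U-, C-, A- and G-ending codons of each targeted
#' box, together with the censoring status of every cell (`ok` measured,
#' `bd` below the 0.2% detection limit, `ne` not evaluated), the
#' independently determined inosine-modification fraction of each anticodon
#' (1.0 for ACG, 0.5 for AUG, 0.15 for AAG, 0 elsewhere) and, where one was
#' published, the printed U3:C3 ratio text. Censored cells carry `NA` means
#' (never 0): the censored-floor rule substitutes the LOD, not zero, in
#' ratio arithmetic.
#'
#' @return Data.frame with one row per anticodon (15 rows), class
#'   `paper_fixture`.
#' @export
paper_fixture <- function() {
  raw <- utils::read.table(.fixture_path(), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  parse_cell <- function(mean_chr, sd_chr) {
    status <- ifelse(mean_chr == "BD", "bd",
                     ifelse(mean_chr == "NE", "ne", "ok"))
    list(mean = ifelse(status == "ok", suppressWarnings(as.numeric(mean_chr)),
                       NA_real_),
         sd = ifelse(status == "ok", suppressWarnings(as.numeric(sd_chr)),
                     NA_real_),
         status = status)
  }
  out <- data.frame(anticodon = raw$anticodon, amino_acid = raw$amino_acid,
                    targeted_codon = raw$targeted_codon,
                    stringsAsFactors = FALSE)
  for (p in c("u", "c", "a", "g")) {
    cell <- parse_cell(raw[[paste0("re_", p)]], raw[[paste0("re_", p, "_sd")]])
    out[[paste0("re_", p)]] <- cell$mean
    out[[paste0("re_", p, "_sd")]] <- cell$sd
    out[[paste0("re_", p, "_status")]] <- cell$status
  }
  out$modification_fraction <- as.numeric(raw$modification_fraction)
  out$printed_ratio <- ifelse(raw$printed_ratio == "NA", NA_character_,
                              raw$printed_ratio)
  class(out) <- c("paper_fixture", "data.frame")
  out
}

#' Long-format reassignment-efficiency table from the fixture
#'
#' Expands the per-anticodon fixture into one row per evaluated
#' (anticodon, codon) pair, the layout consumed by the ratio and
#' concordance stages. Codons are reconstructed from the targeted codon's
#' box prefix plus the column's third base. Below-detection cells are kept
#' (status `bd`, `below_lod = TRUE`, `NA` mean); not-evaluated cells are
#' kept with status `ne`.
#'
#' @param fixture A `paper_fixture` (default: the packaged one).
#' @param lod Limit of detection in percent.
#' @return Data.frame with columns `anticodon`, `codon`, `position3`,
#'   `mean`, `sd`, `below_lod`, `status`.
#' @export
fixture_re_table <- function(fixture = paper_fixture(), lod = 0.2) {
  rows <- list()
  third <- c(u = "U", c = "C", a = "A", g = "G")
  for (i in seq_len(nrow(fixture))) {
    prefix <- substr(fixture$targeted_codon[i], 1L, 2L)
    for (p in names(third)) {
      status <- fixture[[paste0("re_", p, "_status")]][i]
      m <- fixture[[paste0("re_", p)]][i]
      rows[[length(rows) + 1L]] <- data.frame(
        anticodon = fixture$anticodon[i],
        codon = paste0(prefix, third[[p]]),
        position3 = third[[p]],
        mean = m,
        sd = fixture[[paste0("re_", p, "_sd")]][i],
        below_lod = if (status == "bd") TRUE
                    else if (status == "ne") NA
                    else m < lod,
        status = status,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# -- synthetic reference cDNA and fixture traces ---------------------------

# Synthetic flanks around the sequenced anticodon triplet. The tRNA gene
# sequence itself is not bundled, so a synthetic stand-in body provides
# unique, T-containing context on both sides (the T positions double as
# known-unmodified probes for the estimator's noise floor). The right
# flank deliberately starts with A so no C or T peak sits adjacent to the
# quantified position-34 peak, whose T:C signal would otherwise pick up
# tail leakage from its neighbour.
.cdna_left_flank <- "GATTACAGGTTC"
.cdna_right_flank <- "AGCAGTGATTCG"

#' Synthetic reference cDNA for an anticodon
#'
#' Builds the reference sequence for the sequenced (reverse-complement)
#' strand: a synthetic flank, the DNA form of the targeted codon -- which is
#' what the anticodon triplet reads as on this strand, with tRNA position 34
#' as its third base -- in lowercase (marking the triplet for
#' [locate_anticodon()]), and a second synthetic flank.
#'
#' @param anticodon Three-base RNA anticodon.
#' @return Reference cDNA string with the triplet in lowercase.
#' @export
reference_cdna <- function(anticodon) {
  codon_dna <- chartr("U", "T", targeted_codon(anticodon))
  paste0(.cdna_left_flank, tolower(codon_dna), .cdna_right_flank)
}

#' Simulate chromatograms for the 15 fixture anticodons
#'
#' One trace per fixture anticodon, built on the synthetic reference body,
#' with the position-34 peak (the third triplet base) mixed as T/C according
#' to the anticodon's modification fraction. Per-trace seeds are derived
#' from `seed` so the set is reproducible as a whole.
#'
#' @param seed Integer seed for the set.
#' @param fixture A `paper_fixture`.
#' @param ... Further arguments passed to [trace_spec()] (noise, morphology).
#' @return Named list of `chromatogram`s, names = anticodons.
#' @export
simulate_fixture_traces <- function(seed = 1L, fixture = paper_fixture(),
                                    ...) {
  out <- list()
  for (i in seq_len(nrow(fixture))) {
    ac <- fixture$anticodon[i]
    f <- fixture$modification_fraction[i]
    ref <- toupper(reference_cdna(ac))
    pos34 <- nchar(.cdna_left_flank) + 3L
    mixed <- if (f > 0) {
      stats::setNames(list(c(T = 1 - f, C = f)), as.character(pos34))
    } else {
      list()
    }
    spec <- trace_spec(ref, mixed_positions = mixed,
                       seed = seed + i, ...)
    out[[ac]] <- simulate_trace(spec)
  }
  out
}
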