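# Orchestration: screen table -> efficiencies -> discrimination ratios,
# trace files -> modification calls, and wobble-rule concordance scoring.

#' Discrimination-ratio table from a reassignment-efficiency table
#'
#' One ratio per anticodon, computed from the aggregated means of its
#' U-ending and C-ending codons (ratios are never computed per replicate).
#' A censored C-ending efficiency triggers the LOD-substitution floor; a
#' not-evaluated C-ending cell yields an `NA` row.
#'
#' @param re_table Data.frame with columns `anticodon`, `codon` (or
#'   `position3`), `mean`, `below_lod`, `status`, e.g. from
#'   [fixture_re_table()] or [screen_efficiencies()].
#' @param lod Limit of detection in percent.
#' @return Data.frame with columns `anticodon`, `targeted_codon`, `re_u`,
#'   `re_c`, `u_share`, `c_share`, `is_floor`, `ratio` (display text).
#' @export
ratio_table <- function(re_table, lod = 0.2) {
  if (!"position3" %in% names(re_table)) {
    re_table$position3 <- substr(re_table$codon, 3L, 3L)
  }
  if (!"status" %in% names(re_table)) re_table$status <- "ok"
  rows <- list()
  for (ac in unique(re_table$anticodon)) {
    sub <- re_table[re_table$anticodon == ac, , drop = FALSE]
    u <- sub[sub$position3 == "U", , drop = FALSE]
    cc <- sub[sub$position3 == "C", , drop = FALSE]
    if (nrow(u) != 1L) {
      stop(sprintf("anticodon %s lacks a unique U-ending codon row", ac),
           call. = FALSE)
    }
    dr <- NULL
    if (u$status == "ok" && !isTRUE(u$below_lod)) {
      if (nrow(cc) == 1L && cc$status == "ok" && !isTRUE(cc$below_lod)) {
        dr <- discrimination_ratio(u$mean, cc$mean)
      } else if (nrow(cc) == 1L && (cc$status == "bd" ||
                                    isTRUE(cc$below_lod))) {
        dr <- discrimination_floor(u$mean, lod = lod)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      anticodon = ac,
      targeted_codon = u$codon,
      re_u = u$mean,
      re_c = if (nrow(cc) == 1L) cc$mean else NA_real_,
      u_share = if (is.null(dr)) NA_integer_ else dr$u_share,
      c_share = if (is.null(dr)) NA_integer_ else dr$c_share,
      is_floor = if (is.null(dr)) NA else dr$is_floor,
      ratio = if (is.null(dr)) NA_character_ else format_ratio(dr),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Run the screen-quantification stage
#'
#' Accepts either raw measurements (normalized and aggregated via
#' [screen_efficiencies()]) or an already-aggregated efficiency table, and
#' returns the per-codon efficiency table alongside the per-anticodon
#' discrimination ratios. Deterministic given its inputs.
#'
#' @param screen Raw measurement data.frame (with a `construct` column), an
#'   aggregated efficiency table, or a path to a TSV/CSV of raw
#'   measurements.
#' @param lod Limit of detection in percent.
#' @return List with `re_table` and `ratios`.
#' @export
run_screen_analysis <- function(screen, lod = 0.2) {
  if (is.character(screen)) screen <- read_screen_table(screen)
  re_table <- if ("construct" %in% names(screen)) {
    screen_efficiencies(screen, lod = lod)
  } else {
    screen
  }
  list(re_table = re_table, ratios = ratio_table(re_table, lod = lod))
}

#' Run the trace-quantification stage
#'
#' For each trace: locate the anticodon triplet against its reference,
#' integrate the position-34 peak, estimate the inosine fraction, measure
#' the trace's own baseline noise at unmodified T positions, and call
#' modification. Per-trace parse or localization failures are collected in
#' the `error` column and do not abort the run.
#'
#' @param traces Named list of `chromatogram`s or of trace file paths
#'   (`.ab1`/`.xml`/`.csv`); names identify the samples (anticodons).
#' @param references Named character vector of reference cDNA sequences
#'   (lowercase-marked triplets, see [reference_cdna()]); matched to traces
#'   by name. A single unnamed reference is recycled.
#' @param threshold Absolute modification-call threshold (fraction).
#' @param flank Localization context width in bases.
#' @return Data.frame with one row per trace: `sample`, `fraction`,
#'   `noise_mean`, `noise_sd`, `modified`, `error` (NA when clean);
#'   attribute `n_errors` counts failures.
#' @export
run_trace_analysis <- function(traces, references, threshold = 0.05,
                               flank = 12L) {
  stopifnot(length(traces) >= 1L)
  ids <- names(traces)
  if (is.null(ids)) stop("traces must be a named list", call. = FALSE)
  if (length(references) == 1L && is.null(names(references))) {
    references <- stats::setNames(rep(references, length(ids)), ids)
  }
  rows <- list()
  for (id in ids) {
    res <- tryCatch({
      chrom <- traces[[id]]
      if (is.character(chrom)) chrom <- read_trace(chrom)
      ref <- references[[id]]
      if (is.null(ref)) stop(sprintf("no reference for sample '%s'", id))
      locus <- locate_anticodon(chrom, ref, flank = flank)
      fr <- estimate_inosine_fraction(
        integrate_peak(chrom, locus$trace_index))
      noise <- trace_noise_stats(chrom, exclude = locus$anticodon_window)
      call <- call_modification(fr, noise$mean, noise$sd,
                                threshold = threshold)
      data.frame(sample = id, fraction = fr, noise_mean = noise$mean,
                 noise_sd = noise$sd, modified = call$modified,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(sample = id, fraction = NA_real_, noise_mean = NA_real_,
                 noise_sd = NA_real_, modified = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "n_errors") <- sum(!is.na(out$error))
  out
}

#' Score observed decoding against wobble rule sets
#'
#' The measured decoded set of an anticodon is the set of evaluated codons
#' whose reassignment is above the limit of detection. Each anticodon is
#' classified, in precedence order (modification evidence overrides
#' pairing-only explanations):
#'
#' 1. `inosine_like` -- the anticodon is known to be inosine-modified and
#'    decodes at least the U- and C-ending codons;
#' 2. `two_out_of_three` -- the codon box has two G/C prefix bases and the
#'    U-, C- and G-ending codons are all decoded;
#' 3. `wobble_consistent` -- the decoded set is exactly the classical-rules
#'    prediction for A34 (the U-ending codon alone);
#' 4. `anomalous` -- anything else.
#'
#' @param re_table Efficiency table (see [ratio_table()] for the expected
#'   columns).
#' @param modification Named numeric vector of inosine-modified fractions
#'   per anticodon (e.g. fixture values or trace-call fractions); missing
#'   names count as unmodified.
#' @param modified_gate Fraction at or above which an anticodon counts as
#'   modified (default 0.05, the chromatogram visibility threshold).
#' @return Data.frame: `anticodon`, `targeted_codon`, `decoded`
#'   (comma-separated measured set), `predicted_crick`, `box_strength`,
#'   `modified`, `classification`.
#' @export
wobble_concordance <- function(re_table, modification = NULL,
                               modified_gate = 0.05) {
  if (!"position3" %in% names(re_table)) {
    re_table$position3 <- substr(re_table$codon, 3L, 3L)
  }
  if (!"status" %in% names(re_table)) re_table$status <- "ok"
  rows <- list()
  for (ac in unique(re_table$anticodon)) {
    sub <- re_table[re_table$anticodon == ac, , drop = FALSE]
    u <- sub[sub$position3 == "U", , drop = FALSE]
    if (nrow(u) != 1L) {
      stop(sprintf("anticodon %s lacks a unique U-ending codon row", ac),
           call. = FALSE)
    }
    box <- codon_box(u$codon)
    measured <- sub$codon[sub$status == "ok" & !is.na(sub$below_lod) &
                          !sub$below_lod]
    stopifnot(all(measured %in% box$members))
    ends <- substr(measured, 3L, 3L)
    crick <- predicted_codon_set(wobble_base(ac), box, "crick_original")
    mod_fraction <- if (!is.null(modification) && ac %in% names(modification))
      modification[[ac]] else 0
    is_mod <- isTRUE(mod_fraction >= modified_gate)
    classification <-
      if (is_mod && all(c("U", "C") %in% ends)) {
        "inosine_like"
      } else if (box$strength == 2L && all(c("U", "C", "G") %in% ends)) {
        "two_out_of_three"
      } else if (setequal(measured, crick)) {
        "wobble_consistent"
      } else {
        "anomalous"
      }
    rows[[length(rows) + 1L]] <- data.frame(
      anticodon = ac, targeted_codon = u$codon,
      decoded = paste(sort(measured), collapse = ","),
      predicted_crick = paste(crick, collapse = ","),
      box_strength = box$strength,
      modified = is_mod,
      classification = classification,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Read an analysis configuration file
#'
#' YAML (or JSON) with any of: `screen_table`, `trace_files` (named map
#' sample -> path), `reference_cdna` (named map or single sequence), `lod`,
#' `detection_multiple`, `modification_threshold`, `flank`, `rule_sets`,
#' `out_dir`, `seed`. Missing keys fall back to package defaults.
#'
#' @param path Config file path.
#' @return Named list of settings with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(lod = 0.2, detection_multiple = 2,
                   modification_threshold = 0.05, flank = 12L,
                   rule_sets = c("crick_original", "two_out_of_three"),
                   out_dir = ".", seed = 1L)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  if (cfg$lod <= 0) stop("config: lod must be > 0", call. = FALSE)
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis and write reports
#'
#' Screen quantification, discrimination ratios, trace modification calls
#' and wobble concordance, written as `re_table.tsv`, `ratios.tsv`,
#' `modification_calls.tsv`, `concordance.tsv` and `summary.json` under
#' `out_dir`. With no screen input the packaged fixture is analyzed; with
#' no trace input, traces for the fixture anticodons are simulated at the
#' fixture's modification fractions using the configured seed. Identical
#' configuration and seed give byte-identical reports.
#'
#' @param config A configuration list (see [read_config()]) or a path to a
#'   config file.
#' @return Invisibly, a list with `re_table`, `ratios`, `calls`,
#'   `concordance` and `summary`; `summary$n_errors` is nonzero when any
#'   trace failed.
#' @export
run_all <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  defaults <- list(lod = 0.2, modification_threshold = 0.05, flank = 12L,
                   out_dir = NULL, seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }

  fixture <- paper_fixture()
  re_table <- if (!is.null(config$screen_table)) {
    run_screen_analysis(config$screen_table, lod = config$lod)$re_table
  } else {
    fixture_re_table(fixture, lod = config$lod)
  }
  ratios <- ratio_table(re_table, lod = config$lod)

  if (!is.null(config$trace_files)) {
    traces <- config$trace_files
    refs <- unlist(config$reference_cdna)
  } else {
    traces <- simulate_fixture_traces(seed = config$seed, fixture = fixture)
    refs <- vapply(names(traces), reference_cdna, character(1))
  }
  calls <- run_trace_analysis(traces, refs,
                              threshold = config$modification_threshold,
                              flank = config$flank)

  mod <- stats::setNames(calls$fraction, calls$sample)
  mod[is.na(mod)] <- 0
  concordance <- wobble_concordance(re_table, modification = mod,
                                    modified_gate =
                                      config$modification_threshold)

  summary <- list(
    n_anticodons = length(unique(re_table$anticodon)),
    n_modified_calls = sum(calls$modified, na.rm = TRUE),
    n_errors = attr(calls, "n_errors"),
    classifications = as.list(table(concordance$classification))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(re_table, file.path(config$out_dir, "re_table.tsv"))
    .write_tsv(ratios, file.path(config$out_dir, "ratios.tsv"))
    .write_tsv(calls, file.path(config$out_dir, "modification_calls.tsv"))
    .write_tsv(concordance, file.path(config$out_dir, "concordance.tsv"))
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(re_table = re_table, ratios = ratios, calls = calls,
                 concordance = concordance, summary = summary))
}
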