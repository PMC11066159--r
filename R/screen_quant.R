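# Fluorescence screen quantification: normalization against 0%/100%
# reference constructs, replicate aggregation, LOD censoring.

#' Normalize a fluorescence measurement to a reassignment efficiency
#'
#' The screen brackets the mean per-cell fluorescence of the evaluated system
#' between a 100% reference construct (tyrosine encoded at the reporter
#' position) and a 0% reference construct (another amino acid encoded).
#' The reassignment efficiency in percent is the affine map
#' \deqn{100 (x - r_0) / (r_{100} - r_0).}
#' Values outside \[0, 100\] are kept (not clipped) so noisy replicates stay
#' auditable.
#'
#' @param sample,ref0,ref100 Mean per-cell fluorescence values (arbitrary
#'   units, finite and >= 0).
#' @return Reassignment efficiency in percent (may be vectorized over
#'   `sample`).
#' @examples
#' normalize_measurement(5100, 100, 10100) # 50
#' @export
normalize_measurement <- function(sample, ref0, ref100) {
  stopifnot(is.numeric(sample), is.numeric(ref0), is.numeric(ref100),
            length(ref0) == 1L, length(ref100) == 1L)
  if (!all(is.finite(c(sample, ref0, ref100)))) {
    stop("fluorescence values must be finite", call. = FALSE)
  }
  if (any(c(sample, ref0, ref100) < 0)) {
    stop("fluorescence values must be >= 0", call. = FALSE)
  }
  if (ref100 <= ref0) {
    stop("degenerate references: ref100 must exceed ref0", call. = FALSE)
  }
  100 * (sample - ref0) / (ref100 - ref0)
}

#' Aggregate replicate reassignment efficiencies
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator, the
#' standard choice for biological replicates; sd is 0 when n = 1).
#'
#' @param values Numeric vector of per-replicate efficiencies (percent),
#'   length >= 1.
#' @return Object of class `reassignment_efficiency`: list with `mean`, `sd`
#'   and `n` (percent scale); `below_lod` and `lod` are `NA` until
#'   [apply_lod()] is called.
#' @examples
#' aggregate_replicates(c(6, 8)) # mean 7, sd ~1.414
#' @export
aggregate_replicates <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("values must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  structure(
    list(
      mean = mean(values),
      sd = if (n == 1L) 0 else stats::sd(values),
      n = n,
      below_lod = NA,
      lod = NA_real_
    ),
    class = "reassignment_efficiency"
  )
}

#' Censor a reassignment efficiency at the limit of detection
#'
#' The screen's limit of detection, set by residual cell and media
#' fluorescence, is 0.2% reassignment. Means strictly below the LOD are
#' flagged censored (`below_lod = TRUE`); the boundary value counts as
#' detected. The mean itself is preserved for audit -- censored values enter
#' ratio statistics only through the censored-floor rule
#' (see [discrimination_floor()]).
#'
#' @param re A `reassignment_efficiency` (or a bare numeric mean).
#' @param lod Limit of detection in percent (> 0), default 0.2.
#' @return The input with `below_lod` and `lod` filled in.
#' @export
apply_lod <- function(re, lod = 0.2) {
  stopifnot(is.numeric(lod), length(lod) == 1L, lod > 0)
  if (is.numeric(re)) re <- aggregate_replicates(re)
  if (!inherits(re, "reassignment_efficiency")) {
    stop("re must be a reassignment_efficiency or numeric", call. = FALSE)
  }
  re$below_lod <- re$mean < lod
  re$lod <- lod
  re
}

#' @export
print.reassignment_efficiency <- function(x, ...) {
  flag <- if (isTRUE(x$below_lod)) " [below LOD]" else ""
  cat(sprintf("RE %.2f%% ± %.2f (n = %d)%s\n", x$mean, x$sd, x$n, flag))
  invisible(x)
}

#' Read a raw screen measurement table
#'
#' Expects a TSV or CSV file with columns `replicate_id`, `construct`
#' (`sample`, `ref0` or `ref100`), `anticodon`, `codon`, `value`, and an
#' optional `batch` column pairing samples with their reference wells
#' (references are assumed per-batch; a missing column means one global
#' batch).
#'
#' @param path File path; the delimiter is chosen from the extension
#'   (`.csv` vs anything else = tab).
#' @return A data.frame of raw measurements.
#' @export
read_screen_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("replicate_id", "construct", "value")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("screen table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"batch" %in% names(df)) df$batch <- "all"
  df
}

#' Reassignment efficiencies from a raw screen table
#'
#' Normalizes every sample replicate against the mean `ref0`/`ref100` values
#' of its batch, then aggregates replicates per (anticodon, codon) and
#' applies LOD censoring.
#'
#' @param df Raw measurement data.frame as from [read_screen_table()] or
#'   [simulate_screen()]; must contain `construct` and `value`, plus
#'   `anticodon`/`codon` for sample rows (reference rows may leave them
#'   blank).
#' @param lod Limit of detection in percent.
#' @return A data.frame with one row per (anticodon, codon): columns
#'   `anticodon`, `codon`, `mean`, `sd`, `n`, `below_lod`, `status`
#'   (`"ok"`).
#' @export
screen_efficiencies <- function(df, lod = 0.2) {
  if (!"batch" %in% names(df)) df$batch <- "all"
  if (!all(c("construct", "value") %in% names(df))) {
    stop("need 'construct' and 'value' columns", call. = FALSE)
  }
  out <- list()
  for (b in unique(df$batch)) {
    sub <- df[df$batch == b, , drop = FALSE]
    r0 <- sub$value[sub$construct == "ref0"]
    r100 <- sub$value[sub$construct == "ref100"]
    if (!length(r0) || !length(r100)) {
      stop(sprintf("missing reference wells in batch '%s'", b), call. = FALSE)
    }
    smp <- sub[sub$construct == "sample", , drop = FALSE]
    if (!nrow(smp)) next
    key <- paste(smp$anticodon, smp$codon, sep = "|")
    for (k in unique(key)) {
      rows <- smp[key == k, , drop = FALSE]
      pct <- normalize_measurement(rows$value, mean(r0), mean(r100))
      re <- apply_lod(aggregate_replicates(pct), lod = lod)
      out[[length(out) + 1L]] <- data.frame(
        anticodon = rows$anticodon[1], codon = rows$codon[1],
        mean = re$mean, sd = re$sd, n = re$n, below_lod = re$below_lod,
        status = "ok", stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) stop("no sample rows found", call. = FALSE)
  do.call(rbind, out)
}
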