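# Four-channel Sanger chromatogram container plus XML/CSV trace dialects.
# Traces are DNA-alphabet (T, not U): the sequenced strand is cDNA.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a chromatogram
#'
#' A chromatogram is the analyzed four-channel signal of a Sanger trace plus
#' the base caller's output: one peak location (sample index) per called
#' base. Base calling itself is out of scope; called bases and peak
#' locations are taken as given (from the instrument or the simulator).
#'
#' @param channels Named list of four equal-length non-negative numeric
#'   vectors, names `A`, `C`, `G`, `T`.
#' @param peak_locations Strictly increasing integer sample indices
#'   (1-based), one per called base, all within the signal length.
#' @param called_bases DNA string of the same length as `peak_locations`.
#' @param channel_order Four-character permutation of `ACGT` recording the
#'   order channels are stored on disk (ABIF `FWO_` field); purely
#'   informational in memory since `channels` is keyed by base.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(channels, peak_locations, called_bases,
                         channel_order = "ACGT") {
  if (!is.list(channels) || !setequal(names(channels), DNA_BASES)) {
    stop("channels must be a named list with elements A, C, G, T",
         call. = FALSE)
  }
  channels <- lapply(channels[DNA_BASES], as.numeric)
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L || lens[1] == 0L) {
    stop("all four channels must have the same non-zero length",
         call. = FALSE)
  }
  if (any(vapply(channels, function(ch) any(!is.finite(ch) | ch < 0),
                 logical(1)))) {
    stop("channel signals must be finite and non-negative", call. = FALSE)
  }
  peak_locations <- as.integer(peak_locations)
  if (length(peak_locations) == 0L ||
      any(diff(peak_locations) <= 0L) ||
      peak_locations[1] < 1L ||
      peak_locations[length(peak_locations)] > lens[1]) {
    stop("peak_locations must be strictly increasing indices within the trace",
         call. = FALSE)
  }
  called_bases <- toupper(as.character(called_bases))
  if (nchar(called_bases) != length(peak_locations)) {
    stop("called_bases length must match peak_locations", call. = FALSE)
  }
  if (!grepl("^[ACGTN]+$", called_bases)) {
    stop("called_bases must be a DNA string (A, C, G, T, N)", call. = FALSE)
  }
  co <- toupper(channel_order)
  if (nchar(co) != 4L ||
      !setequal(strsplit(co, "")[[1]], DNA_BASES)) {
    stop("channel_order must be a permutation of ACGT", call. = FALSE)
  }
  structure(
    list(channels = channels, peak_locations = peak_locations,
         called_bases = called_bases, channel_order = co),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram: %d samples x 4 channels, %d called bases\n",
              length(x$channels$A), length(x$peak_locations)))
  cat(sprintf("  bases: %s%s\n", substr(x$called_bases, 1, 40),
              if (nchar(x$called_bases) > 40) "..." else ""))
  invisible(x)
}

#' Write a chromatogram to the package's XML trace dialect
#'
#' A simple self-describing dialect: one `<channel base=.../>` element per
#' base (stored in `channel_order` order) holding the space-separated
#' signal, plus `<peak_locations>` and `<called_bases>` elements.
#'
#' @param chrom A `chromatogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_xml <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  doc <- xml2::xml_new_root("trace")
  xml2::xml_add_child(doc, "channel_order", chrom$channel_order)
  for (b in strsplit(chrom$channel_order, "")[[1]]) {
    node <- xml2::xml_add_child(doc, "channel",
                                paste(format(chrom$channels[[b]],
                                             trim = TRUE, scientific = FALSE),
                                      collapse = " "))
    xml2::xml_set_attr(node, "base", b)
  }
  xml2::xml_add_child(doc, "peak_locations",
                      paste(chrom$peak_locations, collapse = " "))
  xml2::xml_add_child(doc, "called_bases", chrom$called_bases)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a chromatogram from the package's XML trace dialect
#'
#' @param path Path to an XML trace written by [write_trace_xml()] (or any
#'   document with the same elements).
#' @return A `chromatogram`.
#' @export
read_trace_xml <- function(path) {
  doc <- xml2::read_xml(path)
  need <- function(xp) {
    node <- xml2::xml_find_all(doc, xp)
    if (length(node) == 0L) {
      stop(sprintf("XML trace is missing element '%s'", xp), call. = FALSE)
    }
    node
  }
  ch_nodes <- need("//channel")
  if (length(ch_nodes) != 4L) {
    stop("XML trace must contain exactly 4 channel elements", call. = FALSE)
  }
  channels <- list()
  for (node in ch_nodes) {
    b <- toupper(xml2::xml_attr(node, "base"))
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
    if (length(vals) == 0L || any(is.na(vals))) {
      stop(sprintf("channel %s is empty or non-numeric", b), call. = FALSE)
    }
    channels[[b]] <- vals
  }
  if (length(unique(lengths(channels))) != 1L) {
    stop("XML trace channels have unequal lengths", call. = FALSE)
  }
  order_node <- xml2::xml_find_first(doc, "//channel_order")
  co <- if (inherits(order_node, "xml_missing")) "ACGT"
        else xml2::xml_text(order_node)
  ploc <- as.integer(strsplit(
    trimws(xml2::xml_text(need("//peak_locations"))), "\\s+")[[1]])
  bases <- trimws(xml2::xml_text(need("//called_bases")))
  chromatogram(channels, ploc, bases, channel_order = co)
}

#' Write a chromatogram as a CSV trace table
#'
#' Long format: one row per sample with columns `index`, `A`, `C`, `G`, `T`;
#' a `call` column carries the called base on rows that are peak locations
#' and is empty elsewhere.
#'
#' @param chrom A `chromatogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  n <- length(chrom$channels$A)
  call <- character(n)
  call[chrom$peak_locations] <-
    strsplit(chrom$called_bases, "")[[1]]
  df <- data.frame(index = seq_len(n),
                   A = chrom$channels$A, C = chrom$channels$C,
                   G = chrom$channels$G, T = chrom$channels$T,
                   call = call, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatogram from a CSV trace table
#'
#' @param path Path to a CSV written by [write_trace_csv()] (columns
#'   `index`, `A`, `C`, `G`, `T`, `call`).
#' @return A `chromatogram`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(call = "character"))
  missing <- setdiff(c("index", DNA_BASES, "call"), names(df))
  if (length(missing)) {
    stop("CSV trace is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$index), , drop = FALSE]
  peak_rows <- which(!is.na(df$call) & nzchar(df$call))
  chromatogram(
    channels = list(A = df$A, C = df$C, G = df$G, T = df$T),
    peak_locations = df$index[peak_rows],
    called_bases = paste(df$call[peak_rows], collapse = "")
  )
}

#' Read a trace file of any supported format
#'
#' Dispatches on file extension: `.ab1` (ABIF binary), `.xml`, `.csv`.
#'
#' @param path Trace file path.
#' @return A `chromatogram`.
#' @export
read_trace <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ab1 = read_abif(path),
    abif = read_abif(path),
    xml = read_trace_xml(path),
    csv = read_trace_csv(path),
    stop(sprintf("unsupported trace format '.%s' (use .ab1, .xml or .csv)",
                 ext), call. = FALSE)
  )
}
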