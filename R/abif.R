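# Minimal ABIF (.ab1) container reader/writer.
#
# ABIF is Applied Biosystems' big-endian tagged binary format. Only the tags
# carrying the analyzed trace are handled: DATA9-DATA12 (the four processed
# signal channels, int16), PLOC (peak locations, int16, 0-based on disk),
# PBAS (called bases, char) and FWO_ (field-wire order: which base each DATA
# channel belongs to). Directory entries whose payload fits in 4 bytes store
# it inline in the offset field, as the container specifies.

.abif_entry_size <- 28L

.be_int <- function(bytes, offset, size, n, signed = TRUE) {
  idx <- (offset + 1L):(offset + size * n)
  if (max(idx) > length(bytes)) {
    stop("ABIF file truncated while reading directory or data",
         call. = FALSE)
  }
  readBin(bytes[idx], "integer", n = n, size = size, endian = "big",
          signed = signed)
}

.be_chars <- function(bytes, offset, n) {
  idx <- (offset + 1L):(offset + n)
  if (max(idx) > length(bytes)) stop("ABIF file truncated", call. = FALSE)
  rawToChar(bytes[idx])
}

.read_entry <- function(bytes, offset) {
  list(
    name = .be_chars(bytes, offset, 4L),
    number = .be_int(bytes, offset + 4L, 4L, 1L),
    elementtype = .be_int(bytes, offset + 8L, 2L, 1L),
    elementsize = .be_int(bytes, offset + 10L, 2L, 1L),
    numelements = .be_int(bytes, offset + 12L, 4L, 1L),
    datasize = .be_int(bytes, offset + 16L, 4L, 1L),
    dataoffset_raw = bytes[(offset + 21L):(offset + 24L)],
    dataoffset = .be_int(bytes, offset + 20L, 4L, 1L)
  )
}

.entry_payload <- function(bytes, entry) {
  if (entry$datasize <= 4L) {
    entry$dataoffset_raw[seq_len(entry$datasize)]
  } else {
    idx <- (entry$dataoffset + 1L):(entry$dataoffset + entry$datasize)
    if (max(idx) > length(bytes)) {
      stop(sprintf("ABIF tag %s%d points past end of file",
                   entry$name, entry$number), call. = FALSE)
    }
    bytes[idx]
  }
}

.decode_payload <- function(entry, payload) {
  switch(as.character(entry$elementtype),
    "2" = rawToChar(payload),                                  # char
    "4" = readBin(payload, "integer", n = entry$numelements,   # int16
                  size = 2L, endian = "big", signed = TRUE),
    "5" = readBin(payload, "integer", n = entry$numelements,   # int32
                  size = 4L, endian = "big", signed = TRUE),
    stop(sprintf("unsupported ABIF element type %d for tag %s",
                 entry$elementtype, entry$name), call. = FALSE)
  )
}

#' Read an ABIF (.ab1) Sanger trace
#'
#' Parses the minimal tag set needed for trace quantification: the four
#' analyzed signal channels `DATA9`-`DATA12`, peak locations `PLOC`, called
#' bases `PBAS` and the channel order `FWO_`. Channels are re-keyed by base
#' through `FWO_`, and peak locations are converted to 1-based indices.
#'
#' @param path Path to an `.ab1` file, or a raw vector of its bytes.
#' @return A [chromatogram()].
#' @seealso [write_abif()] for the matching writer.
#' @export
read_abif <- function(path) {
  bytes <- if (is.raw(path)) path
           else readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 6L || rawToChar(bytes[1:4]) != "ABIF") {
    stop("not an ABIF file (bad magic)", call. = FALSE)
  }
  root <- .read_entry(bytes, 6L)
  if (root$name != "tdir") {
    stop("ABIF directory header not found", call. = FALSE)
  }
  n_entries <- root$numelements
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    entries[[i]] <- .read_entry(bytes,
                                root$dataoffset + (i - 1L) * .abif_entry_size)
  }
  keys <- vapply(entries, function(e) paste0(e$name, e$number), character(1))
  names(entries) <- keys

  fetch <- function(name, numbers) {
    for (num in numbers) {
      e <- entries[[paste0(name, num)]]
      if (!is.null(e)) return(.decode_payload(e, .entry_payload(bytes, e)))
    }
    stop(sprintf("ABIF file is missing required tag %s", name),
         call. = FALSE)
  }

  fwo <- toupper(fetch("FWO_", 1L))
  data_tags <- lapply(9:12, function(num) fetch("DATA", num))
  order_bases <- strsplit(fwo, "")[[1]]
  if (!setequal(order_bases, DNA_BASES)) {
    stop("ABIF FWO_ field is not a permutation of ACGT", call. = FALSE)
  }
  channels <- stats::setNames(data_tags, order_bases)
  ploc <- fetch("PLOC", c(1L, 2L)) + 1L
  pbas <- fetch("PBAS", c(1L, 2L))
  chromatogram(channels, ploc, pbas, channel_order = fwo)
}

.be_raw <- function(values, size) {
  writeBin(as.integer(values), raw(), size = size, endian = "big")
}

.make_entry <- function(name, number, elementtype, elementsize, values) {
  payload <- switch(as.character(elementtype),
    "2" = charToRaw(values),
    "4" = .be_raw(values, 2L),
    stop("unsupported element type in writer")
  )
  n <- if (elementtype == 2L) nchar(values) else length(values)
  list(name = name, number = number, elementtype = elementtype,
       elementsize = elementsize, numelements = n,
       datasize = length(payload), payload = payload)
}

.serialize_entry <- function(entry, dataoffset) {
  c(charToRaw(entry$name),
    .be_raw(entry$number, 4L),
    .be_raw(entry$elementtype, 2L),
    .be_raw(entry$elementsize, 2L),
    .be_raw(entry$numelements, 4L),
    .be_raw(entry$datasize, 4L),
    if (entry$datasize <= 4L) {
      c(entry$payload, raw(4L - entry$datasize))
    } else {
      .be_raw(dataoffset, 4L)
    },
    .be_raw(0L, 4L)) # datahandle
}

#' Write a chromatogram as a minimal ABIF (.ab1) container
#'
#' Produces a valid ABIF file containing `DATA9`-`DATA12` (channels in
#' `channel_order`), `PLOC1`, `PBAS1` and `FWO_1`, parseable by
#' [read_abif()]. Channels are stored as big-endian int16 -- the convention
#' for analyzed traces -- so signal values are rounded to the nearest
#' integer on write and must lie within the int16 range; the round-trip
#' `read_abif(write_abif(x))` is exact for integer-valued chromatograms.
#'
#' @param chrom A `chromatogram`.
#' @param path Output path; if `NULL`, the raw byte vector is returned
#'   instead.
#' @return `path` invisibly, or the raw bytes when `path` is `NULL`.
#' @export
write_abif <- function(chrom, path = NULL) {
  if (!inherits(chrom, "chromatogram")) {
    stop("chrom must be a chromatogram", call. = FALSE)
  }
  vals <- unlist(chrom$channels, use.names = FALSE)
  if (any(abs(vals) > 32767)) {
    stop("channel signals exceed the int16 range of ABIF DATA tags",
         call. = FALSE)
  }
  order_bases <- strsplit(chrom$channel_order, "")[[1]]
  entries <- list()
  for (i in 1:4) {
    entries[[i]] <- .make_entry("DATA", 8L + i, 4L, 2L,
                                round(chrom$channels[[order_bases[i]]]))
  }
  entries[[5]] <- .make_entry("PLOC", 1L, 4L, 2L, chrom$peak_locations - 1L)
  entries[[6]] <- .make_entry("PBAS", 1L, 2L, 1L, chrom$called_bases)
  entries[[7]] <- .make_entry("FWO_", 1L, 2L, 1L, chrom$channel_order)

  header_len <- 128L
  data_blocks <- raw(0)
  offsets <- integer(length(entries))
  cursor <- header_len
  for (i in seq_along(entries)) {
    if (entries[[i]]$datasize > 4L) {
      offsets[i] <- cursor
      data_blocks <- c(data_blocks, entries[[i]]$payload)
      cursor <- cursor + entries[[i]]$datasize
    }
  }
  dir_offset <- cursor
  directory <- raw(0)
  for (i in seq_along(entries)) {
    directory <- c(directory, .serialize_entry(entries[[i]], offsets[i]))
  }
  root <- c(charToRaw("tdir"),
            .be_raw(1L, 4L),
            .be_raw(1023L, 2L),
            .be_raw(.abif_entry_size, 2L),
            .be_raw(length(entries), 4L),
            .be_raw(length(entries) * .abif_entry_size, 4L),
            .be_raw(dir_offset, 4L),
            .be_raw(0L, 4L))
  header <- c(charToRaw("ABIF"), .be_raw(101L, 2L), root)
  header <- c(header, raw(header_len - length(header)))
  out <- c(header, data_blocks, directory)
  if (is.null(path)) return(out)
  writeBin(out, path)
  invisible(path)
}
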