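# Minimal ABIF (Applied Biosystems AB1) container support.
#
# The format is a big-endian tagged directory: a 128-byte header whose
# embedded "tdir" entry points at an array of 28-byte directory entries,
# each naming a (tag, number) record with an element type, count and either
# an offset into the file or, for payloads of <= 4 bytes, the data packed
# into the offset field itself. Only the records a trace viewer needs are
# interpreted: analyzed traces (DATA 9-12), dye base order (FWO_ 1),
# basecalls (PBAS), called-peak locations (PLOC) and qualities (PCON).

ABIF_TYPE_BYTE <- 1L
ABIF_TYPE_CHAR <- 2L
ABIF_TYPE_SHORT <- 4L
ABIF_TYPE_LONG <- 5L
ABIF_TYPE_FLOAT <- 7L
ABIF_TYPE_DOUBLE <- 8L
ABIF_TYPE_PSTRING <- 18L
ABIF_TYPE_CSTRING <- 19L

abif_read_entry <- function(raw, off) {
  # off: 0-based offset of a 28-byte directory entry
  slice <- raw[(off + 1L):(off + 28L)]
  list(
    name = rawToChar(slice[1:4]),
    number = readBin(slice[5:8], "integer", 1, 4, endian = "big"),
    type = readBin(slice[9:10], "integer", 1, 2, endian = "big"),
    elsize = readBin(slice[11:12], "integer", 1, 2, endian = "big"),
    nelem = readBin(slice[13:16], "integer", 1, 4, endian = "big"),
    dsize = readBin(slice[17:20], "integer", 1, 4, endian = "big"),
    doffset_raw = slice[21:24],
    doffset = readBin(slice[21:24], "integer", 1, 4, endian = "big"))
}

abif_entry_data <- function(raw, e) {
  payload <- if (e$dsize <= 4L) e$doffset_raw[seq_len(e$dsize)] else
    raw[(e$doffset + 1L):(e$doffset + e$dsize)]
  switch(as.character(e$type),
    "1" = as.integer(payload),
    "2" = rawToChar(payload),
    "4" = readBin(payload, "integer", e$nelem, 2, signed = TRUE, endian = "big"),
    "5" = readBin(payload, "integer", e$nelem, 4, endian = "big"),
    "7" = readBin(payload, "double", e$nelem, 4, endian = "big"),
    "8" = readBin(payload, "double", e$nelem, 8, endian = "big"),
    "18" = rawToChar(payload[-1L]),              # pString: leading length byte
    "19" = rawToChar(payload[payload != as.raw(0)]),
    payload)
}

#' Read an ABIF (AB1) Sanger trace file
#'
#' Parses the ABIF directory and returns the analyzed (basecaller-processed)
#' trace channels, mapped from the instrument's dye order to A, C, G, T via
#' the file's `FWO_` record, together with the basecalls and called-peak
#' trace locations. Analyzed traces (`DATA` records 9-12) are preferred over
#' raw ones (1-4), matching what trace viewers display and quantify.
#'
#' @param path Path to an AB1 file.
#' @return A [chromatogram()].
#' @export
read_ab1 <- function(path) {
  if (!file.exists(path))
    stop_sangeredit(paste0("file not found: ", path), "sangeredit_format_error")
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128L || rawToChar(raw[1:4]) != "ABIF")
    stop_sangeredit(paste0("not an ABIF file (missing magic): ", path),
                    "sangeredit_format_error")
  tdir <- abif_read_entry(raw, 6L)
  entries <- lapply(seq_len(tdir$nelem) - 1L, function(i)
    abif_read_entry(raw, tdir$doffset + 28L * i))
  keys <- vapply(entries, function(e) paste0(e$name, ".", e$number), "")
  names(entries) <- keys

  get <- function(key) {
    if (!key %in% keys) return(NULL)
    abif_entry_data(raw, entries[[key]])
  }
  need <- function(key) {
    val <- get(key)
    if (is.null(val))
      stop_sangeredit(paste0("ABIF file lacks required record ", key, ": ", path),
                      "sangeredit_content_error")
    val
  }

  # Analyzed channels live in DATA 9-12 when present, raw in DATA 1-4.
  data_ids <- if (all(paste0("DATA.", 9:12) %in% keys)) 9:12 else 1:4
  traces <- lapply(data_ids, function(i) need(paste0("DATA.", i)))
  if (length(unique(lengths(traces))) != 1L)
    stop_sangeredit("trace channels have unequal lengths", "sangeredit_content_error")
  order <- strsplit(toupper(need("FWO_.1")), "")[[1]]
  if (!setequal(order, CHANNEL_BASES))
    stop_sangeredit("FWO_ record is not a permutation of ACGT",
                    "sangeredit_content_error")
  mat <- do.call(cbind, traces)
  colnames(mat) <- order
  mat[mat < 0] <- 0

  basecalls <- get("PBAS.1")
  if (is.null(basecalls)) basecalls <- need("PBAS.2")
  ploc <- get("PLOC.1")
  if (is.null(ploc)) ploc <- need("PLOC.2")
  qual <- get("PCON.1")
  if (is.null(qual)) qual <- get("PCON.2")
  smpl <- get("SMPL.1")
  chromatogram(mat[, CHANNEL_BASES, drop = FALSE], basecalls, ploc,
               sample_id = if (is.null(smpl)) basename(path) else smpl,
               quality = qual, channel_order = order)
}

abif_pack_entry <- function(name, number, type, elsize, nelem, payload, offset,
                            dsize = length(payload)) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw(name), con)
  writeBin(as.integer(number), con, 4, endian = "big")
  writeBin(as.integer(type), con, 2, endian = "big")
  writeBin(as.integer(elsize), con, 2, endian = "big")
  writeBin(as.integer(nelem), con, 4, endian = "big")
  writeBin(as.integer(dsize), con, 4, endian = "big")
  if (length(payload) <= 4L) {
    writeBin(c(payload, raw(4L - length(payload))), con)
  } else {
    writeBin(as.integer(offset), con, 4, endian = "big")
  }
  writeBin(0L, con, 4, endian = "big")   # datahandle
  rawConnectionValue(con)
}

abif_encode <- function(type, values) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  switch(as.character(type),
    "1" = writeBin(as.raw(pmin(pmax(round(values), 0), 255)), con),
    "2" = writeBin(charToRaw(values), con),
    "4" = writeBin(as.integer(values), con, 2, endian = "big"),
    "5" = writeBin(as.integer(values), con, 4, endian = "big"),
    "18" = writeBin(c(as.raw(nchar(values)), charToRaw(values)), con),
    stop("unsupported ABIF write type"))
  rawConnectionValue(con)
}

#' Write a chromatogram as an ABIF (AB1) file
#'
#' Serialises a [chromatogram()] into a minimal but standard-conforming ABIF
#' container (analyzed `DATA` 9-12 records, `FWO_`, `PBAS`, `PLOC`, and
#' `PCON` when quality scores are present) that [read_ab1()] and other ABIF
#' readers can open. Trace values are rounded and clipped to the int16 range
#' used by sequencers.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @param channel_order Dye order to store the four `DATA` records in; the
#'   matching `FWO_` record is written so readers can invert the permutation.
#' @return `path`, invisibly.
#' @export
write_ab1 <- function(chrom, path, channel_order = c("G", "A", "T", "C")) {
  stopifnot(inherits(chrom, "chromatogram"))
  channel_order <- toupper(channel_order)
  if (!setequal(channel_order, CHANNEL_BASES))
    stop_sangeredit("channel_order must be a permutation of ACGT",
                    "sangeredit_content_error")
  tr <- pmin(pmax(round(chrom$traces), 0), 32767L)
  if (max(chrom$peak_locations) > 32767L)
    stop_sangeredit("trace too long for int16 peak locations",
                    "sangeredit_content_error")

  recs <- list()
  for (i in 1:4)
    recs[[length(recs) + 1L]] <- list(name = "DATA", number = 8L + i,
      type = ABIF_TYPE_SHORT, elsize = 2L, nelem = nrow(tr),
      data = abif_encode(4, tr[, channel_order[i]]))
  recs[[length(recs) + 1L]] <- list(name = "FWO_", number = 1L,
    type = ABIF_TYPE_CHAR, elsize = 1L, nelem = 4L,
    data = abif_encode(2, paste(channel_order, collapse = "")))
  recs[[length(recs) + 1L]] <- list(name = "PBAS", number = 1L,
    type = ABIF_TYPE_CHAR, elsize = 1L, nelem = nchar(chrom$basecalls),
    data = abif_encode(2, chrom$basecalls))
  recs[[length(recs) + 1L]] <- list(name = "PLOC", number = 1L,
    type = ABIF_TYPE_SHORT, elsize = 2L, nelem = length(chrom$peak_locations),
    data = abif_encode(4, chrom$peak_locations))
  if (!is.null(chrom$quality))
    recs[[length(recs) + 1L]] <- list(name = "PCON", number = 1L,
      type = ABIF_TYPE_BYTE, elsize = 1L, nelem = length(chrom$quality),
      data = abif_encode(1, chrom$quality))
  recs[[length(recs) + 1L]] <- list(name = "SMPL", number = 1L,
    type = ABIF_TYPE_PSTRING, elsize = 1L, nelem = nchar(chrom$sample_id) + 1L,
    data = abif_encode(18, chrom$sample_id))

  # Lay out payloads after the 128-byte header, then the directory.
  offset <- 128L
  for (i in seq_along(recs)) {
    recs[[i]]$offset <- offset
    if (length(recs[[i]]$data) > 4L)
      offset <- offset + length(recs[[i]]$data)
  }
  dir_offset <- offset

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ABIF"), con)
  writeBin(101L, con, 2, endian = "big")
  writeBin(abif_pack_entry("tdir", 1L, 1023L, 28L, length(recs),
                           raw(5L),   # force offset form
                           dir_offset,
                           dsize = 28L * length(recs))[1:28], con)
  writeBin(raw(128L - 34L), con)
  for (r in recs) if (length(r$data) > 4L) writeBin(r$data, con)
  for (r in recs)
    writeBin(abif_pack_entry(r$name, r$number, r$type, r$elsize, r$nelem,
                             r$data, r$offset), con)
  invisible(path)
}
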