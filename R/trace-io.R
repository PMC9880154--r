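## Sanger chromatogram IO: the ABIF (.ab1) binary container used by Applied
## Biosystems instruments, plus a lossless plain-text TSV dialect for
## fixtures, and peak-based base calling with primary/secondary calls.

#' Construct a chromatogram
#'
#' Four ordered intensity series (channels A, C, G, T) of equal length, plus
#' the scan indices of the called-base peaks.
#'
#' @param A,C,G,T numeric intensity vectors, equal length, non-negative.
#' @param peak_locations strictly increasing scan indices (1-based), one per
#'   called base, all within the channel length.
#' @param sample_id identifier.
#' @param source_format one of "ab1", "tsv", "synthetic".
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(A, C, G, T, peak_locations, sample_id = "sample",
                         source_format = "synthetic") {
  n <- length(A)
  if (length(C) != n || length(G) != n || length(T) != n)
    stop("all four channels must have the same length")
  if (n == 0) stop("chromatogram has zero scans")
  if (any(c(A, C, G, T) < 0)) stop("intensities must be >= 0")
  pl <- as.integer(peak_locations)
  if (length(pl) == 0) stop("chromatogram has no peak locations")
  if (any(diff(pl) <= 0)) stop("peak_locations must be strictly increasing")
  if (pl[1] < 1 || pl[length(pl)] > n)
    stop("peak_locations must fall within the channel length")
  structure(list(channels = cbind(A = as.numeric(A), C = as.numeric(C),
                                  G = as.numeric(G), T = as.numeric(T)),
                 peak_locations = pl, sample_id = sample_id,
                 source_format = source_format),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram '%s': %d scans, %d peaks (%s)\n", x$sample_id,
              nrow(x$channels), length(x$peak_locations), x$source_format))
  invisible(x)
}

## -- ABIF binary format ------------------------------------------------------

.abif_read_entry <- function(con) {
  name <- rawToChar(readBin(con, "raw", 4L))
  number <- readBin(con, "integer", 1L, 4L, endian = "big")
  elem_type <- readBin(con, "integer", 1L, 2L, endian = "big")
  elem_size <- readBin(con, "integer", 1L, 2L, endian = "big")
  n_elem <- readBin(con, "integer", 1L, 4L, endian = "big")
  data_size <- readBin(con, "integer", 1L, 4L, endian = "big")
  offset_raw <- readBin(con, "raw", 4L)
  readBin(con, "raw", 4L)  # data handle, unused
  list(name = name, number = number, elem_type = elem_type,
       elem_size = elem_size, n_elem = n_elem, data_size = data_size,
       offset_raw = offset_raw)
}

.abif_entry_data <- function(raw_all, e) {
  if (e$data_size <= 4L) {
    bytes <- e$offset_raw[seq_len(e$data_size)]
  } else {
    off <- readBin(e$offset_raw, "integer", 1L, 4L, endian = "big")
    if (off + e$data_size > length(raw_all))
      stop(sprintf("AB1 format error: tag %s%d data extends past end of file",
                   e$name, e$number))
    bytes <- raw_all[(off + 1L):(off + e$data_size)]
  }
  switch(as.character(e$elem_type),
         "1" = as.integer(bytes),                                  # byte
         "2" = rawToChar(bytes),                                   # char
         "4" = readBin(bytes, "integer", e$n_elem, 2L,             # short
                       signed = FALSE, endian = "big"),
         "5" = readBin(bytes, "integer", e$n_elem, 4L, endian = "big"),
         bytes)
}

#' Read an AB1 (ABIF) chromatogram
#'
#' Parses the standard ABIF container: processed channel intensities from the
#' `DATA` tags 9-12 (channel order given by the `FWO_` tag) and peak scan
#' locations from `PLOC` (entry 2 preferred, falling back to 1).
#'
#' @param path path to an .ab1 file.
#' @param sample_id identifier; defaults to the file name.
#' @return A [chromatogram()].
#' @export
read_ab1 <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 128L || rawToChar(raw_all[1:4]) != "ABIF")
    stop("AB1 format error: missing ABIF magic header in ", path)
  con <- rawConnection(raw_all)
  on.exit(close(con))
  seek(con, 4L)
  readBin(con, "integer", 1L, 2L, endian = "big")  # version
  tdir <- .abif_read_entry(con)
  if (tdir$name != "tdir") stop("AB1 format error: missing tdir entry")
  dir_off <- readBin(tdir$offset_raw, "integer", 1L, 4L, endian = "big")
  if (dir_off + 28L * tdir$n_elem > length(raw_all))
    stop("AB1 format error: truncated directory")
  seek(con, dir_off)
  entries <- lapply(seq_len(tdir$n_elem), function(i) .abif_read_entry(con))
  find <- function(name, number) {
    for (e in entries) if (e$name == name && e$number == number) return(e)
    NULL
  }
  need <- function(name, number) {
    e <- find(name, number)
    if (is.null(e))
      stop(sprintf("AB1 format error: required tag %s%d not found", name,
                   number))
    e
  }
  fwo <- .abif_entry_data(raw_all, need("FWO_", 1L))
  order_bases <- strsplit(fwo, "")[[1]]
  if (!setequal(order_bases, c("A", "C", "G", "T")))
    stop("AB1 format error: FWO_1 does not enumerate A/C/G/T")
  dat <- lapply(9:12, function(k) .abif_entry_data(raw_all, need("DATA", k)))
  names(dat) <- order_bases
  ploc_e <- find("PLOC", 2L)
  if (is.null(ploc_e)) ploc_e <- need("PLOC", 1L)
  ploc <- .abif_entry_data(raw_all, ploc_e)
  if (is.null(sample_id)) sample_id <- sub("\\.ab1$", "", basename(path))
  chromatogram(A = dat$A, C = dat$C, G = dat$G, T = dat$T,
               peak_locations = ploc + 1L,  # ABIF PLOC is 0-based
               sample_id = sample_id, source_format = "ab1")
}

.abif_pack_entry <- function(name, number, elem_type, elem_size, n_elem,
                             data, offset) {
  data_size <- length(data)
  header <- c(charToRaw(sprintf("%-4s", name)),
              writeBin(as.integer(number), raw(), 4L, endian = "big"),
              writeBin(as.integer(elem_type), raw(), 2L, endian = "big"),
              writeBin(as.integer(elem_size), raw(), 2L, endian = "big"),
              writeBin(as.integer(n_elem), raw(), 4L, endian = "big"),
              writeBin(as.integer(data_size), raw(), 4L, endian = "big"))
  if (data_size <= 4L) {
    off_field <- c(data, raw(4L - data_size))
    data_out <- raw(0)
  } else {
    off_field <- writeBin(as.integer(offset), raw(), 4L, endian = "big")
    data_out <- data
  }
  list(entry = c(header, off_field, raw(4L)), data = data_out)
}

.as_short_raw <- function(x) {
  x <- as.integer(round(pmin(pmax(x, 0), 32767)))
  writeBin(x, raw(), 2L, endian = "big")
}

#' Write a chromatogram to an AB1 (ABIF) file
#'
#' Writes the minimal standard tag set (`DATA` 9-12, `PLOC` 2, `FWO_` 1) that
#' [read_ab1()] and common trace viewers consume. Intensities are clamped to
#' the 16-bit range used by the format.
#'
#' @param chrom a [chromatogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ab1 <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  fwo <- "GATC"  # conventional instrument channel order
  order_bases <- strsplit(fwo, "")[[1]]
  payload <- raw(0)
  specs <- list()
  base_off <- 128L
  add <- function(name, number, elem_type, elem_size, n_elem, data) {
    specs[[length(specs) + 1L]] <<- list(name = name, number = number,
                                         elem_type = elem_type,
                                         elem_size = elem_size,
                                         n_elem = n_elem, data = data)
  }
  for (k in seq_along(order_bases)) {
    b <- order_bases[k]
    add("DATA", 8L + k, 4L, 2L, nrow(chrom$channels),
        .as_short_raw(chrom$channels[, b]))
  }
  add("PLOC", 2L, 4L, 2L, length(chrom$peak_locations),
      .as_short_raw(chrom$peak_locations - 1L))
  add("FWO_", 1L, 2L, 1L, 4L, charToRaw(fwo))

  offset <- base_off
  packed <- list()
  for (s in specs) {
    p <- .abif_pack_entry(s$name, s$number, s$elem_type, s$elem_size,
                          s$n_elem, s$data, offset)
    offset <- offset + length(p$data)
    payload <- c(payload, p$data)
    packed[[length(packed) + 1L]] <- p$entry
  }
  dir_off <- offset
  dir_raw <- do.call(c, packed)
  tdir <- .abif_pack_entry("tdir", 1L, 1023L, 28L, length(specs),
                           raw(5L), dir_off)
  tdir$entry[17:20] <- writeBin(as.integer(28L * length(specs)), raw(), 4L,
                                endian = "big")
  tdir$entry[21:24] <- writeBin(as.integer(dir_off), raw(), 4L,
                                endian = "big")
  header <- c(charToRaw("ABIF"),
              writeBin(101L, raw(), 2L, endian = "big"),
              tdir$entry[1:28])
  header <- c(header, raw(128L - length(header)))
  writeBin(c(header, payload, dir_raw), path)
  invisible(path)
}

## -- plain-text trace dialect ------------------------------------------------

#' Read / write the plain-text chromatogram dialect
#'
#' A TSV with columns `scan_index` (1-based, consecutive), `A`, `C`, `G`, `T`
#' (non-negative intensities) and `is_peak` (0/1). The round trip
#' `read_trace_tsv(write_trace_tsv(x))` is lossless.
#'
#' @param path file path.
#' @param sample_id identifier; defaults to the file name.
#' @return A [chromatogram()].
#' @export
read_trace_tsv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("trace TSV format error: ",
                                          conditionMessage(e)))
  need <- c("scan_index", "A", "C", "G", "T", "is_peak")
  if (nrow(df) == 0) stop("trace TSV format error: file has no data rows")
  if (!all(need %in% names(df)))
    stop("trace TSV format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (cn in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop(sprintf("trace TSV format error: non-numeric %s at line %d",
                   cn, bad[1] + 1L))
  }
  if (any(diff(df$scan_index) <= 0))
    stop(sprintf("trace TSV format error: non-monotone scan_index at line %d",
                 which(diff(df$scan_index) <= 0)[1] + 2L))
  if (any(df[, c("A", "C", "G", "T")] < 0)) {
    bad <- which(rowSums(df[, c("A", "C", "G", "T")] < 0) > 0)[1]
    stop(sprintf("trace TSV format error: negative intensity at line %d",
                 bad + 1L))
  }
  if (is.null(sample_id)) sample_id <- sub("\\.tsv$", "", basename(path))
  chromatogram(A = df$A, C = df$C, G = df$G, T = df$T,
               peak_locations = df$scan_index[df$is_peak == 1],
               sample_id = sample_id, source_format = "tsv")
}

#' @rdname read_trace_tsv
#' @param chrom a [chromatogram()].
#' @export
write_trace_tsv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  n <- nrow(chrom$channels)
  df <- data.frame(scan_index = seq_len(n),
                   A = chrom$channels[, "A"], C = chrom$channels[, "C"],
                   G = chrom$channels[, "G"], T = chrom$channels[, "T"],
                   is_peak = as.integer(seq_len(n) %in% chrom$peak_locations))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## -- base calling ------------------------------------------------------------

#' Call primary and secondary bases from a chromatogram
#'
#' At each peak location the primary call is the channel with the maximum
#' amplitude; the secondary call is the second-highest channel when its
#' amplitude reaches `secondary_threshold` times the maximum (the usual
#' mixed-base convention), otherwise it repeats the primary call. Ties break
#' deterministically in channel order A < C < G < T. A peak with zero
#' amplitude in all four channels is called N and flagged.
#'
#' @param chrom a [chromatogram()].
#' @param secondary_threshold fraction of the primary amplitude a second
#'   channel must reach, in (0, 1\]; default 0.33.
#' @return A `base_calls` object: list with `primary` and `secondary`
#'   (character scalars, IUPAC), `per_base_intensity` (n x 4 matrix of channel
#'   amplitudes at the peaks), `flagged` (logical, all-zero peaks), and
#'   `sample_id`.
#' @export
call_bases <- function(chrom, secondary_threshold = 0.33) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (secondary_threshold <= 0 || secondary_threshold > 1)
    stop("secondary_threshold must lie in (0, 1]")
  amp <- chrom$channels[chrom$peak_locations, , drop = FALSE]
  bases <- colnames(amp)
  n <- nrow(amp)
  primary <- secondary <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    a <- amp[i, ]
    if (all(a == 0)) {
      primary[i] <- secondary[i] <- "N"
      flagged[i] <- TRUE
      next
    }
    ord <- order(-a, seq_along(a))  # stable: A < C < G < T on ties
    primary[i] <- bases[ord[1]]
    secondary[i] <- if (a[ord[2]] >= secondary_threshold * a[ord[1]])
      bases[ord[2]] else bases[ord[1]]
  }
  structure(list(primary = paste(primary, collapse = ""),
                 secondary = paste(secondary, collapse = ""),
                 per_base_intensity = amp,
                 flagged = flagged,
                 sample_id = chrom$sample_id),
            class = "base_calls")
}

#' @export
print.base_calls <- function(x, ...) {
  cat(sprintf("base_calls '%s': %d bases, %d flagged\n", x$sample_id,
              nchar(x$primary), sum(x$flagged)))
  invisible(x)
}
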