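## Formats: multichannel TIFF, annotation JSON, cell-table CSV, YAML config.

#' Write a multichannel image as a multi-page float TIFF
#'
#' One page per channel, uncompressed 32-bit IEEE float (sample format 3),
#' little-endian, with the channel name stored in each page's
#' ImageDescription tag. Written by hand because the available TIFF
#' bindings only store scaled integers; any standard TIFF reader
#' (including [tiff::readTIFF()]) reads the result losslessly at float32
#' precision.
#'
#' @param image `H x W x C` numeric array (channel dimnames used if
#'   present) or a single matrix.
#' @param path Output path.
#' @param channels Optional channel names (default: dimnames or C1..Cn).
#' @return `path`, invisibly.
#' @export
write_multiplex_tiff <- function(image, path, channels = NULL) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  nch <- dim(image)[3]
  h <- dim(image)[1]; w <- dim(image)[2]
  channels <- channels %||% dimnames(image)[[3]] %||%
    paste0("C", seq_len(nch))
  ## pad names to >= 4 chars so the NUL-terminated ASCII payload always
  ## exceeds 4 bytes and lives behind an offset (trimmed again on read)
  desc <- formatC(channels, width = 4, flag = "-")
  desc_len <- nchar(desc, "bytes") + 1L
  strip_bytes <- 4L * h * w
  strip_off <- 8L + (seq_len(nch) - 1L) * strip_bytes
  ifd_size <- 2L + 11L * 12L + 4L
  ifd_off <- 8L + nch * strip_bytes +
    c(0L, cumsum(ifd_size + desc_len))[seq_len(nch)]
  desc_off <- ifd_off + ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  wb4 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  entry <- function(tag, type, count, value) {
    wb2(tag); wb2(type); wb4(count)
    if (type == 3) { wb2(value); wb2(0) } else wb4(value)
  }
  writeBin(charToRaw("II"), con); wb2(42L); wb4(ifd_off[1])
  for (i in seq_len(nch))
    writeBin(as.numeric(t(image[, , i])), con, size = 4,
             endian = "little")
  for (i in seq_len(nch)) {
    wb2(11L)
    entry(256L, 4L, 1L, w)                       # ImageWidth
    entry(257L, 4L, 1L, h)                       # ImageLength
    entry(258L, 3L, 1L, 32L)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # no compression
    entry(262L, 3L, 1L, 1L)                      # black is zero
    entry(270L, 2L, desc_len[i], desc_off[i])    # ImageDescription
    entry(273L, 4L, 1L, strip_off[i])            # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, 1L, h)                       # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, 3L)                      # SampleFormat: IEEE float
    wb4(if (i < nch) ifd_off[i + 1] else 0L)
    writeBin(c(charToRaw(desc[i]), as.raw(0)), con)
  }
  invisible(path)
}

#' Read a multichannel TIFF into an image array
#'
#' Channel names come from the per-page ImageDescription tags when
#' present; otherwise pages are assumed to follow the panel order
#' ([panel_channels()]), skipping any markers listed in `zero_fill`.
#' Channels in `zero_fill` are inserted as all-zero channels (the
#' treatment of an unstained marker, such as CD20 in prostate panels,
#' whose channel is set to 0 before processing).
#'
#' @param path TIFF path (one page per channel).
#' @param zero_fill Optional character vector of missing channel names to
#'   insert as zeros.
#' @param channels Channel names of the stored pages, in page order
#'   (overrides tags and the panel default). Use with `expect = NULL` for
#'   non-panel stacks such as label maps.
#' @param expect Final channel set and order (default the 7-channel
#'   panel); NULL to accept any.
#' @return `H x W x C` array with channel dimnames.
#' @export
read_multiplex_tiff <- function(path, zero_fill = NULL, channels = NULL,
                                expect = panel_channels()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  tags <- vapply(pages, function(p)
    trimws(as.character(attr(p, "description") %||% "")), character(1))
  nm <- channels %||%
    (if (all(tags != "")) tags
     else if (!is.null(expect)) setdiff(expect, zero_fill)
     else paste0("C", seq_along(pages)))
  if (length(nm) != length(pages))
    stop("expected ", length(nm), " channels, found ", length(pages),
         " (check `zero_fill` for missing markers)")
  img <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, nm))
  for (ch in zero_fill) {
    zero <- array(0, dim = c(dim(img)[1:2], 1),
                  dimnames = list(NULL, NULL, ch))
    dn <- c(dimnames(img)[[3]], ch)
    img <- array(c(img, zero), dim = dim(img) + c(0, 0, 1),
                 dimnames = list(NULL, NULL, dn))
  }
  if (!is.null(expect)) {
    if (dim(img)[3] != length(expect))
      stop("expected ", length(expect), " channels, found ", dim(img)[3],
           " (use `zero_fill` for missing markers)")
    img <- img[, , expect, drop = FALSE]
  }
  img
}

#' Write annotations to JSON
#'
#' Schema: `{tile_id, annotations: [{x, y, kind, likert: {CD3, FOXP3,
#' CD20, CD45RO, CD8}}]}`; background annotations carry no `likert`.
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @param tile_id Tile identifier string.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, tile_id = "tile") {
  mk <- phenotyping_markers()
  items <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- list(x = annotations$x[i], y = annotations$y[i],
              kind = annotations$kind[i])
    if (annotations$kind[i] == "cell")
      a$likert <- as.list(setNames(
        as.numeric(annotations[i, paste0("likert_", mk)]), mk))
    a
  })
  jsonlite::write_json(list(tile_id = tile_id, annotations = items), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from JSON
#'
#' @param path JSON path (see [write_annotations()] for the schema).
#' @return An [annotation_set()]; the tile id is attached as attribute
#'   `tile_id`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mk <- phenotyping_markers()
  items <- j$annotations
  lik <- do.call(rbind, lapply(items, function(a) {
    v <- vapply(mk, function(m)
      as.numeric(a$likert[[m]] %||% NA_real_), numeric(1))
    as.data.frame(as.list(v))
  }))
  out <- annotation_set(
    x = vapply(items, function(a) as.numeric(a$x), numeric(1)),
    y = vapply(items, function(a) as.numeric(a$y), numeric(1)),
    kind = vapply(items, function(a) as.character(a$kind), character(1)),
    likert = lik)
  attr(out, "tile_id") <- j$tile_id
  out
}

#' Write a detection table to CSV
#'
#' UTF-8, comma-separated, `.` decimal; floats at 6 significant digits.
#'
#' @param detections Detection table (see [detect_and_phenotype()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(detections, path) {
  out <- detections
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a detection table from CSV
#'
#' @param path CSV written by [write_cell_table()].
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such cell table: ", path)
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
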