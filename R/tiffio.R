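# Minimal baseline TIFF support: little-endian, uncompressed, single-sample
# pages (32-bit float cubes, 32-bit integer masks). No R TIFF reader is
# available in the target environment, so multi-page cube I/O is implemented
# directly; the format subset is the baseline profile that tifffile and
# ImageJ read without trouble. Wavelengths are carried in each page's
# ImageDescription as "wavelength_nm=<value>".

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L,
               ImageDescription = 270L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

tiff_entry <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "little")

# serialise one IFD; `data_offset` is where this page's pixel strip lives
write_ifd <- function(con, entries, next_ifd) {
  write_u16(con, length(entries))
  for (e in entries) {
    write_u16(con, e$tag)
    write_u16(con, e$type)
    write_u32(con, e$count)
    if (e$type == 2L) {             # ASCII, always via offset here
      write_u32(con, e$value)
    } else if (e$type == 3L && e$count == 1L) {  # SHORT inline, pad
      write_u16(con, e$value); write_u16(con, 0L)
    } else {                        # LONG inline
      write_u32(con, e$value)
    }
  }
  write_u32(con, next_ifd)
}

#' Write a multispectral cube as a multi-page 32-bit float TIFF
#'
#' One uncompressed grayscale page per band, little-endian, with the band's
#' wavelength recorded in the page's ImageDescription tag as
#' `wavelength_nm=<value>`.
#'
#' @param cube H x W x B numeric array, or a `tissue_cube`.
#' @param path output path.
#' @param wavelengths length-B numeric; taken from the `tissue_cube` if
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_cube_tiff <- function(cube, path, wavelengths = NULL) {
  if (inherits(cube, "tissue_cube")) {
    if (is.null(wavelengths)) wavelengths <- cube$wavelengths
    cube <- cube$cube
  }
  stopifnot(length(dim(cube)) == 3)
  B <- dim(cube)[3]
  if (is.null(wavelengths)) wavelengths <- rep(NA_real_, B)
  stopifnot(length(wavelengths) == B)
  pages <- lapply(seq_len(B), function(b) cube[, , b])
  descs <- sprintf("wavelength_nm=%s", wavelengths)
  write_tiff_pages(pages, path, sample_format = 3L, bits = 32L,
                   descriptions = descs)
}

#' Write an integer label mask as a single-page TIFF
#' @param mask H x W integer matrix (0 = background).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  write_tiff_pages(list(mask), path, sample_format = 2L, bits = 32L,
                   descriptions = "label mask")
}

write_tiff_pages <- function(pages, path, sample_format, bits, descriptions) {
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  bytes_px <- bits %/% 8L
  strip_bytes <- H * W * bytes_px
  n_entries <- length(TIFF_TAGS)
  ifd_bytes <- 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u16(con, 42L)
  # layout per page: [description][pixel strip][IFD]
  offset <- 8L
  desc_raw <- lapply(descriptions, function(d) c(charToRaw(d), as.raw(0L)))
  page_size <- vapply(desc_raw, length, 1L) + strip_bytes + ifd_bytes
  desc_off <- offset + c(0L, cumsum(page_size))[seq_along(pages)]
  strip_off <- desc_off + vapply(desc_raw, length, 1L)
  ifd_off <- strip_off + strip_bytes
  write_u32(con, ifd_off[1])
  for (p in seq_along(pages)) {
    writeBin(desc_raw[[p]], con)
    m <- pages[[p]]
    v <- as.vector(t(m))            # row-major pixel order
    if (sample_format == 3L)
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    else
      writeBin(as.integer(v), con, size = 4, endian = "little")
    entries <- list(
      tiff_entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, W),
      tiff_entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, H),
      tiff_entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bits),
      tiff_entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      tiff_entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L),
      tiff_entry(TIFF_TAGS[["ImageDescription"]], 2L,
                 length(desc_raw[[p]]), desc_off[p]),
      tiff_entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, strip_off[p]),
      tiff_entry(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      tiff_entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, H),
      tiff_entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, strip_bytes),
      tiff_entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, sample_format))
    write_ifd(con, entries, if (p < length(pages)) ifd_off[p + 1] else 0L)
  }
  invisible(path)
}

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
read_u32 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
    65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
}

read_tag_values <- function(raw, off, type, count) {
  sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  sz <- sizes[[as.character(type)]]
  total <- sz * count
  voff <- if (total <= 4L) off else read_u32(raw, off)
  vals <- numeric(count)
  for (k in seq_len(count)) {
    o <- voff + (k - 1L) * sz
    vals[k] <- switch(as.character(type),
                      `1` = as.integer(raw[o + 1]),
                      `2` = as.integer(raw[o + 1]),
                      `3` = read_u16(raw, o),
                      `4` = read_u32(raw, o))
  }
  vals
}

#' Read a multi-page TIFF written by this package (or a compatible
#' uncompressed little-endian baseline TIFF)
#'
#' @param path file path.
#' @return For multi-band files, a list with `cube` (H x W x B array) and
#'   `wavelengths` (NA where no `wavelength_nm=` description is present);
#'   single-page integer files return the same structure with B = 1 — use
#'   [read_mask_tiff()] for masks.
#' @export
read_cube_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian TIFF is supported")
  if (read_u16(raw, 2L) != 42L) stop("not a TIFF file")
  ifd_off <- read_u32(raw, 4L)
  pages <- list()
  wl <- numeric(0)
  while (ifd_off != 0L) {
    n <- read_u16(raw, ifd_off)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2L + (k - 1L) * 12L
      tag <- read_u16(raw, e)
      type <- read_u16(raw, e + 2L)
      count <- read_u32(raw, e + 4L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        off = e + 8L)
    }
    gettag <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) return(default)
      read_tag_values(raw, t$off, t$type, t$count)
    }
    W <- gettag(256); H <- gettag(257)
    bits <- gettag(258, 8L)[1]
    comp <- gettag(259, 1L)
    fmt <- gettag(339, 1L)[1]
    if (comp != 1L) stop("compressed TIFF is not supported")
    offs <- gettag(273)
    counts <- gettag(279)
    # wavelength from ImageDescription, if present
    dtag <- tags[["270"]]
    w <- NA_real_
    if (!is.null(dtag)) {
      doff <- if (dtag$count <= 4L) dtag$off else read_u32(raw, dtag$off)
      desc <- rawToChar(raw[(doff + 1):(doff + dtag$count - 1L)])
      m <- regmatches(desc, regexpr("wavelength_nm=[-0-9.eE+]+", desc))
      if (length(m) == 1) w <- as.numeric(sub("wavelength_nm=", "", m))
    }
    npx <- H * W
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seg <- raw[(offs[s] + 1):(offs[s] + counts[s])]
      vals <- c(vals, if (fmt == 3L)
        readBin(seg, "double", n = counts[s] %/% (bits %/% 8L),
                size = bits %/% 8L, endian = "little")
        else
          readBin(seg, "integer", n = counts[s] %/% (bits %/% 8L),
                  size = bits %/% 8L, endian = "little",
                  signed = !(fmt == 1L && bits < 32L)))
    }
    pages[[length(pages) + 1L]] <- matrix(vals[seq_len(npx)], nrow = H,
                                          byrow = TRUE)
    wl <- c(wl, w)
    ifd_off <- read_u32(raw, ifd_off + 2L + n * 12L)
  }
  cube <- array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                                       length(pages)))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]]
  list(cube = cube, wavelengths = wl)
}

#' @rdname read_cube_tiff
#' @export
read_mask_tiff <- function(path) {
  r <- read_cube_tiff(path)
  m <- r$cube[, , 1]
  storage.mode(m) <- "integer"
  m
}
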