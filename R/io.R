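#' Read a grayscale TIFF image or plane stack
#'
#' Single-channel 2D images or multi-page stacks, 8/16-bit integer or
#' 32-bit float. Integer values are widened to float and preserved
#' exactly. Images written by [write_image()] with a range sidecar
#' (`<path>.range.json`) are mapped back to their original intensity
#' scale. RGB/multichannel pages are rejected.
#'
#' @param path TIFF file path.
#' @param pixel_size nm/px to attach as attribute; when `NA`, the TIFF
#'   resolution tags are used if present (inch or cm units), else the
#'   attribute stays `NA`.
#' @return A numeric matrix (single page) or `H x W x P` array (stack),
#'   with attribute `pixel_size`.
#' @export
read_image <- function(path, pixel_size = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("empty TIFF: ", path)
  # the reader normalizes integer pages to [0, 1]; raw integer values come
  # from an as.is read (which garbles float pages, so both reads are
  # compared to tell the sample formats apart)
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  planes <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    d <- dim(p)
    if (length(d) == 3) {
      if (d[3] > 1)
        stop("unsupported multichannel TIFF: page ", i, " has ", d[3],
             " samples per pixel")
      p <- p[, , 1]
    }
    bps <- attr(pages[[i]], "bits.per.sample")
    r <- raw[[i]]
    if (length(dim(r)) == 3) r <- r[, , 1]
    storage.mode(r) <- "double"
    if (!is.null(bps) &&
        max(abs(r / (2^bps - 1) - p)) < 1e-9) {
      p <- r  # integer page: keep the exact stored values
    }
    storage.mode(p) <- "double"
    p
  })
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    planes <- lapply(planes, function(p) {
      if (identical(rng$dtype, "uint16")) p <- p / 65535
      p * (rng$max - rng$min) + rng$min
    })
  }
  if (is.na(pixel_size)) {
    info <- pages[[1]]
    xres <- attr(info, "x.resolution")
    unit <- attr(info, "resolution.unit")
    if (!is.null(xres) && length(xres) && is.finite(xres) && xres > 0 &&
        !is.null(unit)) {
      pixel_size <- switch(as.character(unit),
                           inch = 2.54e7 / xres, cm = 1e7 / xres, NA)
    }
  }
  out <- if (length(planes) == 1) planes[[1]]
         else array(unlist(planes), dim = c(dim(planes[[1]]),
                                            length(planes)))
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Write an image or plane stack as grayscale TIFF
#'
#' Float (32-bit) by default. Values outside `[0, 1]` are affinely mapped
#' into `[0, 1]` for storage and the mapping is recorded in a
#' `<path>.range.json` sidecar which [read_image()] inverts, so pixel
#' values round-trip (exactly up to 32-bit float precision).
#' `dtype = "uint16"` quantizes to 16 bits with the same recorded mapping.
#'
#' @param x numeric matrix or `H x W x P` array with finite values.
#' @param path output path.
#' @param dtype `"float"` or `"uint16"`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(x, path, dtype = c("float", "uint16")) {
  dtype <- match.arg(dtype)
  if (length(x) == 0) stop("empty image")
  if (anyNA(x) || any(!is.finite(x))) stop("image contains NaN/Inf")
  planes <- if (is.matrix(x)) list(x)
            else if (is.array(x) && length(dim(x)) == 3)
              lapply(seq_len(dim(x)[3]), function(k) x[, , k])
            else stop("x must be a matrix or H x W x P array")
  mn <- min(x); mx <- max(x)
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) unlink(sidecar)
  need_scale <- dtype == "uint16" || mn < 0 || mx > 1
  if (need_scale) {
    span <- if (mx > mn) mx - mn else 1
    planes <- lapply(planes, function(p) (p - mn) / span)
    jsonlite::write_json(list(dtype = dtype, min = mn, max = mn + span),
                         sidecar, auto_unbox = TRUE, digits = NA)
  }
  bits <- if (dtype == "float") 32L else 16L
  tiff::writeTIFF(if (length(planes) == 1) planes[[1]] else planes,
                  path, bits.per.sample = bits, compression = "none")
  invisible(path)
}
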