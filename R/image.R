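# Visual-field images: plain numeric matrices that carry their own geometry
# (degrees per pixel and the visual-field coordinates of the first pixel), so
# no stage downstream has to assume a pixel<->degree conversion.
#
# Convention: element [i, j] is row i (y, increasing downward in the matrix
# but upward in degrees via the origin/step), column j (x).  The modeled
# field is the left hemifield, x <= 0.

#' Construct a visual-field image
#'
#' @param values Numeric matrix of intensities (or contrast energy).
#' @param deg_per_px Degrees of visual field per pixel (scalar).
#' @param origin `c(x, y)` visual-field coordinates, in degrees, of the center
#'   of pixel `[1, 1]`.
#' @return Object of class `vf_image`.
#' @export
vf_image <- function(values, deg_per_px, origin = c(0, 0)) {
  stopifnot(is.matrix(values), is.numeric(values), deg_per_px > 0,
            length(origin) == 2)
  structure(list(values = values, deg_per_px = deg_per_px,
                 origin = as.numeric(origin)),
            class = "vf_image")
}

#' @export
print.vf_image <- function(x, ...) {
  cat(sprintf("vf_image %d x %d px, %.4f deg/px, origin (%.2f, %.2f) deg\n",
              nrow(x$values), ncol(x$values), x$deg_per_px,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# x (column) and y (row) coordinates, in degrees, of every pixel center
vf_x <- function(img) img$origin[1] + (seq_len(ncol(img$values)) - 1) * img$deg_per_px
vf_y <- function(img) img$origin[2] + (seq_len(nrow(img$values)) - 1) * img$deg_per_px

#' Read a grayscale image (PNG or plain PGM)
#'
#' PNG files require the `png` package; PGM files must be plain-text (P2).
#' Intensities are rescaled to `[0, 1]`.
#'
#' @param path File path.
#' @param deg_per_px,origin Geometry to attach (see [vf_image()]).
#' @return A `vf_image`.
#' @export
read_image <- function(path, deg_per_px, origin = c(0, 0)) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG images requires the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    vals <- a
  } else if (ext %in% c("pgm", "pnm")) {
    vals <- read_pgm(path)
  } else stop("unsupported image format: ", ext)
  vf_image(vals, deg_per_px, origin)
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only plain-text (P2) PGM is supported")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) / maxv
}

#' Write a plain-text PGM image
#'
#' @param img A `vf_image` (values are clipped to `[0, 1]`).
#' @param path Output path.
#' @param maxval Integer grayscale ceiling.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  v <- round(pmin(pmax(img$values, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# deg_per_px %.8g origin %.8g %.8g",
                       img$deg_per_px, img$origin[1], img$origin[2]),
               paste(ncol(v), nrow(v)), as.character(maxval)), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

# FFT convolution with reflection padding.  The image is mirror-padded by the
# kernel half-width, then zero-padded up to sizes with small prime factors so
# the FFT inside EBImage::filter2 stays fast; the result is cropped back.
conv2_reflect <- function(x, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  if (hr >= nr || hc >= nc)
    stop(sprintf(paste("kernel support (%d x %d) exceeds image size (%d x %d);",
                       "supply an image of at least %d x %d pixels"),
                 kr, kc, nr, nc, kr, kc))
  ri <- c(rev(seq_len(hr) + 1L), seq_len(nr), nr - seq_len(hr))
  ci <- c(rev(seq_len(hc) + 1L), seq_len(nc), nc - seq_len(hc))
  xp <- x[ri, ci, drop = FALSE]
  gr <- stats::nextn(nrow(xp), c(2, 3, 5)); gc <- stats::nextn(ncol(xp), c(2, 3, 5))
  pad <- matrix(0, gr, gc)
  pad[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  out <- EBImage::filter2(pad, kern, boundary = "circular")
  out[hr + seq_len(nr), hc + seq_len(nc), drop = FALSE]
}
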