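#' Binary shape images
#'
#' A `shape_image` is an L x L matrix of 0/1 pixels on the image domain
#' Omega, with 1 marking the shape (foreground) and 0 the background.
#' Pixel coordinates are 1-based with x indexing columns and y indexing
#' rows, so `pixels[y, x]` is the pixel at (x, y); pixel centers sit at
#' integer coordinates.
#'
#' @param pixels square numeric matrix with entries 0/1.
#' @param id optional identifier carried through reports.
#' @return an object of class `shape_image` with fields `L`, `pixels`, `id`.
#' @export
shape_image <- function(pixels, id = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("shape image must be a square matrix", call. = FALSE)
  L <- nrow(pixels)
  if (L < 2)
    stop("shape image must be at least 2 x 2", call. = FALSE)
  if (!all(pixels %in% c(0, 1)))
    stop("shape image entries must be exactly 0 or 1", call. = FALSE)
  nf <- sum(pixels)
  if (nf == 0 || nf == length(pixels))
    stop("degenerate shape: image must contain both foreground and background pixels",
         call. = FALSE)
  structure(list(L = L, pixels = matrix(as.numeric(pixels), L, L), id = id),
            class = "shape_image")
}

#' @export
print.shape_image <- function(x, ...) {
  cat(sprintf("shape_image: %d x %d, %d foreground pixels%s\n",
              x$L, x$L, sum(x$pixels),
              if (is.null(x$id)) "" else paste0(" (id: ", x$id, ")")))
  invisible(x)
}

#' An ordered collection of equally sized shape images
#'
#' @param images list of [shape_image] objects sharing one grid side L.
#' @param ids progeny identifiers (defaults to image ids or seq_along).
#' @return an object of class `shape_set` with fields `images`, `ids`, `L`, `n`.
#' @export
shape_set <- function(images, ids = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  if (!all(vapply(images, inherits, logical(1), "shape_image")))
    stop("all elements must be shape_image objects", call. = FALSE)
  Ls <- vapply(images, function(im) im$L, integer(1))
  if (length(unique(Ls)) != 1)
    stop("all images in a shape_set must share the same grid side L", call. = FALSE)
  if (is.null(ids)) {
    ids <- vapply(seq_along(images), function(i) {
      if (is.null(images[[i]]$id)) paste0("progeny_", i) else as.character(images[[i]]$id)
    }, character(1))
  }
  stopifnot(length(ids) == length(images))
  structure(list(images = images, ids = as.character(ids),
                 L = Ls[1], n = length(images)),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat(sprintf("shape_set: %d images, %d x %d\n", x$n, x$L, x$L))
  invisible(x)
}

#' @export
length.shape_set <- function(x) x$n

#' Read a binary shape from PNG, PGM, or a plain-text 0/1 matrix
#'
#' Grayscale intensities are scaled to \[0, 1\] and thresholded: pixels with
#' scaled intensity strictly above `threshold` become foreground. The
#' text dialect is whitespace-delimited, one image row per line.
#'
#' @param path file path; format is chosen by extension (`.png`, `.pgm`,
#'   anything else is read as a text matrix).
#' @param threshold binarisation threshold in (0, 1); default 0.5.
#' @param id optional identifier stored on the image.
#' @return a [shape_image].
#' @export
load_shape <- function(path, threshold = 0.5, id = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  ext <- tolower(tools::file_ext(path))
  gray <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- a[, , 1]  # first channel of RGB(A)
      a
    },
    pgm = read_pgm(path),
    {
      m <- as.matrix(read.table(path, header = FALSE))
      dimnames(m) <- NULL
      m
    })
  if (nrow(gray) != ncol(gray))
    stop(sprintf("image in '%s' is not square (%d x %d)", path, nrow(gray), ncol(gray)),
         call. = FALSE)
  rng <- range(gray)
  scaled <- if (rng[2] > rng[1]) (gray - rng[1]) / (rng[2] - rng[1]) else gray
  pix <- (scaled > threshold) * 1
  nf <- sum(pix)
  if (nf == 0 || nf == length(pix))
    stop(sprintf("degenerate shape in '%s': thresholding left no %s pixels", path,
                 if (nf == 0) "foreground" else "background"), call. = FALSE)
  shape_image(pix, id = id)
}

# PGM reader for P2 (ASCII) and P5 (binary, maxval <= 255) dialects.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5"))
    stop("not a P2/P5 PGM file: ", path, call. = FALSE)
  # header tokens (width, height, maxval), skipping comments
  toks <- integer(0)
  buf <- character(0)
  while (length(toks) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      toks <- c(toks, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  vals <- if (magic == "P5") {
    if (maxval > 255) stop("16-bit PGM not supported", call. = FALSE)
    as.integer(readBin(con, "raw", w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a shape image
#'
#' `write_shape_text()` writes the whitespace-delimited 0/1 dialect (one
#' image row per line); `write_shape_png()` writes an 8-bit grayscale PNG
#' with foreground white; `write_shape_pgm()` writes ASCII P2.
#'
#' @param image a [shape_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_text <- function(image, path) {
  stopifnot(inherits(image, "shape_image"))
  writeLines(apply(image$pixels, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_shape_text
#' @export
write_shape_png <- function(image, path) {
  stopifnot(inherits(image, "shape_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' @rdname write_shape_text
#' @export
write_shape_pgm <- function(image, path) {
  stopifnot(inherits(image, "shape_image"))
  lines <- c("P2", paste(image$L, image$L), "255",
             apply(image$pixels * 255, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Lexicographic (column-major) vectorisation of a square grid
#'
#' Stacks the columns of an L x L grid sequentially into one vector of
#' length m = L^2, so output index `(c - 1) * L + r` holds the entry at
#' row r, column c. This is the ordering used to turn a signed-distance
#' grid into a phenotype vector.
#'
#' @param m square numeric matrix.
#' @return numeric vector of length `nrow(m)^2`.
#' @export
vectorize_lexicographic <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("vectorize_lexicographic needs a square matrix", call. = FALSE)
  dim(m) <- NULL
  m
}

#' Inverse of [vectorize_lexicographic()]
#'
#' @param v numeric vector of length `L^2`.
#' @param L grid side.
#' @return an L x L matrix with `vectorize_lexicographic(unvectorize(v, L))`
#'   identical to `v`.
#' @export
unvectorize <- function(v, L) {
  if (length(v) != L * L)
    stop(sprintf("vector length %d is not L^2 = %d", length(v), L * L), call. = FALSE)
  matrix(v, nrow = L, ncol = L)
}
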