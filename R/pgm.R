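#' Read / write single-channel grayscale images (PGM)
#'
#' Minimal portable-graymap I/O used for per-channel fluorescence planes.
#' Both the ASCII (`P2`) and binary (`P5`, 8- or 16-bit big-endian) variants
#' are supported; `write_pgm()` emits `P2` by default so fixtures stay plain
#' text. Pixel values are returned as a numeric matrix (rows = image rows).
#'
#' @param path file path.
#' @return `read_pgm()`: numeric matrix of intensities.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_token(con)
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (expected P2 or P5): ", path, call. = FALSE)
  }
  w <- as.integer(read_token(con))
  h <- as.integer(read_token(con))
  maxval <- as.integer(read_token(con))
  npx <- w * h
  if (magic == "P2") {
    vals <- numeric(0)
    while (length(vals) < npx) {
      chunk <- scan(con, what = numeric(), n = npx - length(vals),
                    quiet = TRUE, comment.char = "#")
      if (!length(chunk)) break
      vals <- c(vals, chunk)
    }
    if (length(vals) < npx) stop("truncated PGM: ", path, call. = FALSE)
  } else {
    size <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, what = "integer", n = npx, size = size,
                    signed = FALSE, endian = "big")
    if (length(vals) < npx) stop("truncated PGM: ", path, call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

read_token <- function(con) {
  # whitespace-delimited token, skipping '#' comments
  tok <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || !nzchar(ch)) {
      if (nzchar(tok)) return(tok)
      stop("unexpected end of PGM header", call. = FALSE)
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) return(tok)
    } else {
      tok <- paste0(tok, ch)
    }
  }
}

#' @rdname read_pgm
#' @param img numeric matrix of non-negative intensities.
#' @param maxval maximum gray value recorded in the header (default the
#'   smallest of 255/65535 covering the data).
#' @param ascii write ASCII `P2` (default) or binary `P5`.
#' @export
write_pgm <- function(img, path, maxval = NULL, ascii = TRUE) {
  stopifnot(is.matrix(img))
  img <- round(img)
  img[img < 0] <- 0
  if (is.null(maxval)) maxval <- if (max(img) > 255) 65535L else 255L
  img[img > maxval] <- maxval
  h <- nrow(img); w <- ncol(img)
  vals <- as.integer(t(img)) # row-major
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    # 12 values per line keeps lines short
    lines <- tapply(vals, (seq_along(vals) - 1L) %/% 12L, paste,
                    collapse = " ")
    writeLines(unname(lines), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", w, h, maxval), con, eos = NULL)
    writeBin(vals, con, size = if (maxval > 255) 2L else 1L, endian = "big")
  }
  invisible(path)
}
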