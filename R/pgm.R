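# Minimal PGM (portable graymap) reader/writer, P2 (ASCII) and P5 (binary).
# Written in-package: none of the installed image packages handle PNM.

#' Read a PGM image into an integer matrix
#'
#' Supports the P2 (ASCII) and P5 (binary, maxval <= 255) variants, with
#' `#` comments in the header.
#'
#' @param path Path to a `.pgm` file.
#' @return Integer matrix (rows x cols) of gray levels.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop(sprintf("'%s' is not a P2/P5 PGM file", path), call. = FALSE)

  # read header tokens (width, height, maxval), skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header", call. = FALSE)
    if (ch == "#") { # skip to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (grepl("\\s", ch) && length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  n <- w * h
  if (magic == "P5") {
    if (maxval > 255) stop("16-bit P5 PGM not supported", call. = FALSE)
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM pixel data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an integer matrix as a PGM image
#'
#' @param mat Numeric matrix of non-negative integers.
#' @param path Output path.
#' @param ascii Write P2 (ASCII) if `TRUE` (default), else P5 (binary).
#' @param maxval Maximum gray value declared in the header (default
#'   `max(mat, 1)`).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path, ascii = TRUE, maxval = NULL) {
  mat <- round(mat)
  if (any(mat < 0)) stop("PGM pixels must be non-negative", call. = FALSE)
  if (is.null(maxval)) maxval <- max(mat, 1)
  if (maxval > 255 && !ascii) stop("P5 output limited to maxval 255", call. = FALSE)
  h <- nrow(mat); w <- ncol(mat)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), as.character(maxval)), con)
    # one image row per line
    apply(mat, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", w, h, maxval), con, eos = NULL)
    writeBin(as.raw(t(mat)), con)
  }
  invisible(path)
}
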