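# 4x4 bipolar pixel patterns. Pixels are +1/-1, stored row-major with row 1
# at the top; "keys" number the pixels 1..16 in the same row-major order.

#' Create a 4x4 bipolar pattern
#'
#' @param pixels 16 values, each +1 or -1, row-major with row 1 at the top.
#' @param name Optional label.
#' @return An object of class `eoect_pattern`.
#' @examples
#' p <- pattern_from_keys(c(1, 2, 3, 6, 10, 14), name = "T_left")
#' print(p)
#' @export
pattern <- function(pixels, name = NULL) {
  px <- suppressWarnings(as.integer(pixels))
  if (length(px) != 16L || anyNA(px)) {
    stop("a pattern needs exactly 16 numeric pixels", call. = FALSE)
  }
  if (!all(px %in% c(-1L, 1L))) {
    stop("pattern pixels must all be +1 or -1", call. = FALSE)
  }
  structure(list(pixels = px, name = name), class = "eoect_pattern")
}

#' Build a pattern from the keys (1-16) of its +1 pixels
#'
#' @param keys Integer key indices in 1..16 set to +1; all others are -1.
#' @param name Optional label.
#' @return An `eoect_pattern`.
#' @export
pattern_from_keys <- function(keys, name = NULL) {
  keys <- as.integer(keys)
  if (length(keys) && (anyNA(keys) || any(keys < 1L | keys > 16L))) {
    stop("keys must lie in 1..16", call. = FALSE)
  }
  px <- rep(-1L, 16L)
  px[keys] <- 1L
  pattern(px, name = name)
}

#' Keys (1-16) of the +1 pixels of a pattern
#' @param p An `eoect_pattern`.
#' @return Integer vector of key indices.
#' @export
positive_keys <- function(p) {
  stopifnot(inherits(p, "eoect_pattern"))
  which(p$pixels == 1L)
}

.pattern_matrix <- function(p) matrix(p$pixels, nrow = 4, ncol = 4, byrow = TRUE)

#' Invert a pattern (flip every pixel)
#' @param p An `eoect_pattern`.
#' @return The negated `eoect_pattern`.
#' @export
pattern_negate <- function(p) {
  stopifnot(inherits(p, "eoect_pattern"))
  nm <- if (is.null(p$name)) NULL else paste0("-", p$name)
  pattern(-p$pixels, name = nm)
}

#' Rotate a pattern 90 degrees clockwise
#' @param p An `eoect_pattern`.
#' @param name Optional label for the rotated pattern.
#' @return The rotated `eoect_pattern`.
#' @export
pattern_rotate_cw <- function(p, name = NULL) {
  m <- .pattern_matrix(p)
  rot <- t(m[4:1, , drop = FALSE])
  pattern(as.integer(t(rot)), name = name)
}

#' Translate a pattern one column to the right
#'
#' Pixels shifted off the right edge are dropped; the vacated left column is
#' filled with -1 (background).
#'
#' @param p An `eoect_pattern`.
#' @param name Optional label for the shifted pattern.
#' @return The shifted `eoect_pattern`.
#' @export
pattern_shift_right <- function(p, name = NULL) {
  m <- .pattern_matrix(p)
  shifted <- cbind(rep(-1L, 4), m[, 1:3, drop = FALSE])
  pattern(as.integer(t(shifted)), name = name)
}

#' Bipolar dot product of two patterns
#'
#' Agreements minus disagreements; ranges from -16 to +16 and equals
#' `16 - 2 * hamming distance`.
#'
#' @param a,b `eoect_pattern` objects.
#' @return Integer in -16..16.
#' @export
pattern_dot <- function(a, b) {
  stopifnot(inherits(a, "eoect_pattern"), inherits(b, "eoect_pattern"))
  sum(a$pixels * b$pixels)
}

#' @export
format.eoect_pattern <- function(x, ...) {
  m <- .pattern_matrix(x)
  apply(m, 1, function(row) paste(ifelse(row == 1L, "#", "."), collapse = ""))
}

#' @export
print.eoect_pattern <- function(x, ...) {
  if (!is.null(x$name)) cat(x$name, "\n")
  cat(format(x), sep = "\n")
  invisible(x)
}

# -- pattern file I/O ---------------------------------------------------------

#' Parse a pattern from ASCII-grid lines
#'
#' The grid format is 4 lines of 4 characters, `#` for +1 and `.` for -1;
#' blank lines and surrounding whitespace are ignored.
#'
#' @param lines Character vector of lines (or one string with newlines).
#' @param name Optional label.
#' @return An `eoect_pattern`.
#' @export
pattern_from_ascii <- function(lines, name = NULL) {
  if (length(lines) == 1L) lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 4L || any(nchar(lines) != 4L)) {
    stop("ASCII pattern must be 4 lines of 4 characters", call. = FALSE)
  }
  chars <- strsplit(paste(lines, collapse = ""), "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("#", "."))) {
    stop("ASCII pattern alphabet is '#' (+1) and '.' (-1)", call. = FALSE)
  }
  pattern(ifelse(chars == "#", 1L, -1L), name = name)
}

#' Read a pattern from a file
#'
#' JSON files (`.json`) must contain `{"name": ..., "pixels": [...]}`; any
#' other extension is parsed as an ASCII grid.
#'
#' @param path File path.
#' @return An `eoect_pattern`.
#' @export
read_pattern_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$pixels)) stop("JSON pattern needs a 'pixels' field", call. = FALSE)
    pattern(obj$pixels, name = obj$name)
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    pattern_from_ascii(readLines(path), name = nm)
  }
}

#' Write a pattern to a file
#'
#' @param p An `eoect_pattern`.
#' @param path Destination; `.json` writes JSON, anything else the ASCII grid.
#' @return `path`, invisibly.
#' @export
write_pattern_file <- function(p, path) {
  stopifnot(inherits(p, "eoect_pattern"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(name = p$name, pixels = p$pixels), path,
                         auto_unbox = TRUE, null = "null")
  } else {
    writeLines(format(p), path)
  }
  invisible(path)
}
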