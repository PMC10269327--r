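# XYZ geometry files. Files are in the standard chemical XYZ dialect with
# coordinates in Angstrom; internally everything is bohr/hartree. The
# conversion constant is pinned here and nowhere else.

#' Bohr per Angstrom conversion constant
#' @export
BOHR_PER_ANGSTROM <- 1.8897259886

#' Molecular structure container
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix `N x 3`, coordinates in bohr.
#' @param comment single comment string.
#' @return an object of class `xyz_structure`.
#' @export
structure_xyz <- function(symbols, coords, comment = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(symbols) == nrow(coords))
  structure(list(symbols = as.character(symbols), coords = unname(coords),
                 comment = as.character(comment)[1]),
            class = "xyz_structure")
}

#' Read a structure from an XYZ file
#'
#' Standard dialect: atom-count line, comment line, then one
#' `element x y z` line per atom (coordinates in Angstrom, converted to bohr).
#' Malformed count or coordinate lines raise an error naming the line number.
#'
#' @param path file path.
#' @return an `xyz_structure` (coordinates in bohr).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("read_xyz: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("read_xyz: empty file (line 1)")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("read_xyz: invalid atom count on line 1")
  if (length(lines) < n + 2) {
    stop(sprintf("read_xyz: expected %d atom lines but file ends at line %d",
                 n, length(lines)))
  }
  comment <- if (length(lines) >= 2) lines[2] else ""
  symbols <- character(n)
  coords <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 4) {
      stop(sprintf("read_xyz: malformed coordinate line %d", ln))
    }
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (any(is.na(xyz))) {
      stop(sprintf("read_xyz: non-numeric coordinates on line %d", ln))
    }
    symbols[i] <- toks[1]
    coords[i, ] <- xyz * BOHR_PER_ANGSTROM
  }
  structure_xyz(symbols, coords, comment)
}

#' Write a structure to an XYZ file
#'
#' Coordinates are written in Angstrom with 12 significant digits. Output is
#' deterministic for a fixed input.
#'
#' @param structure an `xyz_structure` (coordinates in bohr).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  stopifnot(inherits(structure, "xyz_structure"))
  n <- length(structure$symbols)
  ang <- structure$coords / BOHR_PER_ANGSTROM
  lines <- c(as.character(n), structure$comment)
  if (n > 0) {
    lines <- c(lines, vapply(seq_len(n), function(i) {
      sprintf("%-3s %20.12f %20.12f %20.12f", structure$symbols[i],
              ang[i, 1], ang[i, 2], ang[i, 3])
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("<xyz_structure> %d atoms: %s\n", length(x$symbols),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}
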