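#' Parse a Gromacs .gro coordinate file
#'
#' Reads the fixed-column Gromacs coordinate format: a free-text title line,
#' an atom-count line, one line per atom, and a final box line. Atom lines
#' are sliced by character position (residue number cols 1-5, residue name
#' 6-10, atom name 11-15, atom number 16-20, then `%8.3f` coordinate fields),
#' never split on whitespace, so files with merged columns (common in
#' deposited data, e.g. five-digit residue numbers running into the name
#' field) still parse. Velocity columns (`%8.4f`) are detected from line
#' length. Coordinates are in nanometres, velocities in nm/ps.
#'
#' @param x path to a `.gro` file, or the file content as a character vector
#'   of lines (a single string with embedded newlines is also accepted).
#' @return an object of class `gro_system`: a list with `title`,
#'   `n_atoms`, `atoms` (data.frame with columns `residue_number`,
#'   `residue_name`, `atom_name`, `atom_number`, `x`, `y`, `z` and, when
#'   present, `vx`, `vy`, `vz`) and `box` (numeric, 3 or 9 values).
#' @examples
#' txt <- gen_gro(data.frame(residue_name = "SOL", n_residues = 1,
#'                           atoms_per_residue = 3), seed = 1)
#' sys <- parse_gro(txt)
#' sys$n_atoms
#' table(sys$atoms$residue_name)
#' @seealso [gen_gro()], [categorize_residues()]
#' @export
parse_gro <- function(x) {
  lines <- as_lines(x)
  if (length(lines) < 2L) {
    stop("not a .gro file: fewer than 2 lines", call. = FALSE)
  }
  title <- lines[1L]
  n_atoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n_atoms) || n_atoms < 0L) {
    stop("malformed .gro file: atom-count line is not a non-negative integer: ",
         dQuote(trimws(lines[2L])), call. = FALSE)
  }
  if (length(lines) - 3L < n_atoms) {
    stop(sprintf("truncated .gro file: expected %d atom lines, found %d",
                 n_atoms, max(length(lines) - 3L, 0L)), call. = FALSE)
  }
  atoms <- parse_gro_atoms(lines[seq_len(n_atoms) + 2L])
  box_line <- lines[n_atoms + 3L]
  box <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1L]]))
  if (length(box) == 0L || anyNA(box)) {
    stop("malformed .gro file: box line is not numeric", call. = FALSE)
  }
  if (nrow(atoms) > 0L && any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("malformed .gro file: non-finite coordinates", call. = FALSE)
  }
  structure(
    list(title = title, n_atoms = n_atoms, atoms = atoms, box = box),
    class = "gro_system"
  )
}

# Fixed-column slicing of .gro atom lines; velocities by line width.
parse_gro_atoms <- function(lines) {
  n <- length(lines)
  col <- function(from, to) substr(lines, from, to)
  num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- data.frame(
    residue_number = suppressWarnings(as.integer(col(1L, 5L))),
    residue_name   = trimws(col(6L, 10L)),
    atom_name      = trimws(col(11L, 15L)),
    atom_number    = suppressWarnings(as.integer(col(16L, 20L))),
    x = num(col(21L, 28L)), y = num(col(29L, 36L)), z = num(col(37L, 44L)),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(atoms)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    bad <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))[1L]
    stop(sprintf("malformed .gro atom line %d: %s", bad, dQuote(lines[bad])),
         call. = FALSE)
  }
  if (all(nchar(lines) >= 68L)) {
    atoms$vx <- num(col(45L, 52L))
    atoms$vy <- num(col(53L, 60L))
    atoms$vz <- num(col(61L, 68L))
  }
  atoms
}

as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
}

#' @export
print.gro_system <- function(x, ...) {
  cat("Gromacs system: ", x$title, "\n", sep = "")
  cat("  atoms: ", x$n_atoms, "\n", sep = "")
  res <- unique(x$atoms$residue_name)
  cat("  residues: ", paste(utils::head(res, 10L), collapse = ", "),
      if (length(res) > 10L) ", ..." else "", "\n", sep = "")
  cat("  box (nm): ", paste(format(x$box), collapse = " "), "\n", sep = "")
  invisible(x)
}
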