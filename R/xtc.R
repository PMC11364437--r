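#' Summarise a Gromacs .xtc trajectory without decompressing coordinates
#'
#' `.xtc` files are big-endian XDR binary: every frame starts with the magic
#' number 1995, the atom count, the step number, the time stamp (ps) and the
#' 3x3 box, followed by the coordinate block (plain floats for systems of at
#' most 9 atoms, otherwise a compressed payload preceded by its byte count).
#' The reader walks the frame headers and *skips* coordinate payloads, so
#' counting frames in multi-gigabyte trajectories needs neither
#' decompression nor loading the file into memory — the same information
#' `gmx check` reports.
#'
#' @param x path to an `.xtc` file, or a raw vector with its bytes.
#' @return list with `n_atoms`, `n_frames`, `first_time_ps`, `last_time_ps`
#'   (`NA` when the file has no complete frame) and `truncated` (`TRUE` when
#'   the file ends inside a frame; the partial frame is not counted).
#' @examples
#' bytes <- gen_xtc(n_atoms = 3, times = c(0, 10, 20))
#' read_xtc_info(bytes)
#' @seealso [gen_xtc()]
#' @export
read_xtc_info <- function(x) {
  con <- if (is.raw(x)) rawConnection(x, "rb") else file(x, "rb")
  on.exit(close(con))
  XTC_MAGIC <- 1995L
  n_atoms <- NA_integer_
  n_frames <- 0L
  first_time <- NA_real_
  last_time <- NA_real_
  truncated <- FALSE
  repeat {
    header <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    if (length(header) == 0L) break            # clean end of file
    if (length(header) < 3L) { truncated <- TRUE; break }
    if (header[1L] != XTC_MAGIC) {
      if (n_frames == 0L) {
        stop("not an .xtc file: first frame magic is ", header[1L],
             ", expected 1995", call. = FALSE)
      }
      stop("corrupt .xtc file: bad magic at frame index ", n_frames,
           call. = FALSE)
    }
    frame_atoms <- header[2L]
    if (is.na(n_atoms)) {
      n_atoms <- frame_atoms
    } else if (frame_atoms != n_atoms) {
      stop("inconsistent .xtc file: frame ", n_frames, " has ", frame_atoms,
           " atoms, expected ", n_atoms, call. = FALSE)
    }
    tm <- readBin(con, "numeric", n = 10L, size = 4L, endian = "big")
    if (length(tm) < 10L) { truncated <- TRUE; break }
    time_ps <- tm[1L]                           # then 9 box floats
    natoms2 <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    if (length(natoms2) < 1L) { truncated <- TRUE; break }
    if (frame_atoms <= 9L) {
      xyz <- readBin(con, "numeric", n = 3L * frame_atoms, size = 4L,
                     endian = "big")
      if (length(xyz) < 3L * frame_atoms) { truncated <- TRUE; break }
    } else {
      sub <- readBin(con, "integer", n = 9L, size = 4L, endian = "big")
      if (length(sub) < 9L) { truncated <- TRUE; break }
      nbytes <- sub[9L]                         # precision + 6 bounds + smallidx
      if (nbytes < 0L) stop("corrupt .xtc file: negative payload size",
                            call. = FALSE)
      padded <- 4L * ((nbytes + 3L) %/% 4L)
      payload <- readBin(con, "raw", n = padded)
      if (length(payload) < padded) { truncated <- TRUE; break }
    }
    if (n_frames == 0L) first_time <- time_ps
    last_time <- time_ps
    n_frames <- n_frames + 1L
  }
  if (n_frames == 0L) {
    first_time <- NA_real_
    last_time <- NA_real_
    if (is.na(n_atoms)) n_atoms <- 0L
  }
  list(n_atoms = n_atoms, n_frames = n_frames,
       first_time_ps = first_time, last_time_ps = last_time,
       truncated = truncated)
}

# readBin on size-4 integers with the compressed-payload float `precision`
# would misread: XDR floats must be read as "numeric" size 4. The 9 ints
# above deliberately reinterpret the precision float's bytes as an integer;
# only element 9 (the byte count) is used, which really is an integer.
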