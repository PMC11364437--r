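# Minimal STORE-only zip writer used by the fixture generator, so synthetic
# corpora carry real archives that `unzip`/utils::unzip can open. Only the
# features needed for small text members are implemented (no compression,
# no zip64, no directories beyond implicit member paths).

.crc32_table <- local({
  tab <- integer(256L)
  poly <- -306674912L # 0xEDB88320 as a signed 32-bit integer
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(poly, bitwShiftR(c, 1L))
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

# CRC-32 (IEEE, reflected) of a raw vector, returned as signed 32-bit int.
crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(.crc32_table[idx + 1L], bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")

#' Write a STORED (uncompressed) zip archive
#'
#' @param members named list: member path -> raw vector or character content.
#' @param zipfile output path.
#' @return `zipfile`, invisibly.
#' @keywords internal
write_stored_zip <- function(members, zipfile) {
  stopifnot(is.list(members), length(names(members)) == length(members))
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- integer(length(members))
  crcs <- integer(length(members))
  sizes <- integer(length(members))
  pos <- 0L
  for (i in seq_along(members)) {
    name <- names(members)[i]
    data <- members[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
    offsets[i] <- pos
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    nm <- charToRaw(name)
    write_u32(con, 0x04034b50L)        # local file header
    write_u16(con, 20L); write_u16(con, 0L); write_u16(con, 0L)
    write_u16(con, 0L); write_u16(con, 0x21L)  # dummy DOS time/date
    write_u32(con, crcs[i]); write_u32(con, sizes[i]); write_u32(con, sizes[i])
    write_u16(con, length(nm)); write_u16(con, 0L)
    writeBin(nm, con)
    writeBin(data, con)
    pos <- pos + 30L + length(nm) + sizes[i]
  }
  cd_start <- pos
  for (i in seq_along(members)) {
    nm <- charToRaw(names(members)[i])
    write_u32(con, 0x02014b50L)        # central directory entry
    write_u16(con, 20L); write_u16(con, 20L); write_u16(con, 0L); write_u16(con, 0L)
    write_u16(con, 0L); write_u16(con, 0x21L)
    write_u32(con, crcs[i]); write_u32(con, sizes[i]); write_u32(con, sizes[i])
    write_u16(con, length(nm)); write_u16(con, 0L); write_u16(con, 0L)
    write_u16(con, 0L); write_u16(con, 0L); write_u32(con, 0L)
    write_u32(con, offsets[i])
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  write_u32(con, 0x06054b50L)          # end of central directory
  write_u16(con, 0L); write_u16(con, 0L)
  write_u16(con, length(members)); write_u16(con, length(members))
  write_u32(con, pos - cd_start); write_u32(con, cd_start)
  write_u16(con, 0L)
  invisible(zipfile)
}
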