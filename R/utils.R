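#' @keywords internal
"_PACKAGE"

REPOSITORIES <- c("zenodo", "figshare", "osf")

check_repo <- function(repo) {
  if (length(repo) != 1L || !repo %in% REPOSITORIES) {
    stop("unknown repository: ", paste(repo, collapse = ", "),
         " (must be one of ", paste(REPOSITORIES, collapse = ", "), ")",
         call. = FALSE)
  }
  repo
}

#' Extract the lowercase file extension of a path
#'
#' The extension is the lowercased text after the final dot of the base name;
#' compound suffixes keep only the last token (`"x.tar.gz"` gives `"gz"`).
#' Names without a dot (or with nothing after it) map to `"none"`, the
#' bucket used for extensionless files in repository statistics.
#'
#' @param path character vector of file names or paths.
#' @return character vector of extensions, never empty strings.
#' @examples
#' file_extension(c("traj.XTC", "README", "a/b.tar.gz", "run.mdp"))
#' @export
file_extension <- function(path) {
  base <- basename(as.character(path))
  ext <- sub(".*\\.", "", base)
  ext <- tolower(ext)
  ext[!grepl(".", base, fixed = TRUE) | ext == ""] <- "none"
  ext
}

# Normalize heterogeneous repository dates to ISO-8601 (YYYY-MM-DD).
# Accepts ISO (optionally with time), DD/MM/YYYY, and epoch seconds.
normalize_date <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}", x)
  out[iso] <- substr(x[iso], 1L, 10L)
  dmy <- grepl("^\\d{2}/\\d{2}/\\d{4}$", x)
  out[dmy] <- vapply(x[dmy], function(d) {
    p <- strsplit(d, "/", fixed = TRUE)[[1L]]
    paste(p[3L], p[2L], p[1L], sep = "-")
  }, character(1L))
  num <- !iso & !dmy & grepl("^\\d+$", x)
  out[num] <- format(as.Date(as.POSIXct(as.numeric(x[num]),
                                        origin = "1970-01-01", tz = "UTC")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scalar_chr <- function(x) {
  if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x[[1L]])
}

# Replace embedded tabs/newlines so free text stays on one TSV cell.
sanitize_cell <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  gsub("[\t\r\n]+", " ", x)
}

slug <- function(x) {
  x <- gsub("[^A-Za-z0-9]+", "-", as.character(x))
  x <- gsub("^-+|-+$", "", x)
  ifelse(x == "", "empty", tolower(x))
}
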