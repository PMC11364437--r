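#' Search an index snapshot
#'
#' Case-insensitive substring matching of each keyword against dataset
#' title, description and file names. All filters are conjunctive. Results
#' are ranked by score — the number of distinct keywords that matched in
#' any searched field — descending, then publication date descending, then
#' dataset id. An empty query with no filters returns every dataset.
#'
#' @param index an `md_index`.
#' @param keywords character vector of search terms (may be empty).
#' @param repository,engine,extension optional filters: keep datasets from
#'   this repository / holding at least one file assigned to this engine /
#'   holding at least one file with this extension.
#' @param date_from,date_to optional ISO dates bounding the publication
#'   date (inclusive).
#' @param size_min,size_max optional bounds on the dataset's total size in
#'   bytes.
#' @param search_zip_members match keywords against zip-member names too,
#'   and let zip members satisfy the engine/extension filters (default
#'   `TRUE`).
#' @param map extension -> engine lookup for the engine filter.
#' @return data.frame of class `md_search_results`: one row per matching
#'   dataset with `repository`, `dataset_id`, `doi`, `title`,
#'   `publication_date`, `score`, `n_matching_files`, ordered by rank. The
#'   matching file rows are in `attr(, "files")`.
#' @examples
#' # index <- load_snapshot("snapshot/")
#' # hits <- search_index(index, keywords = c("martini", "membrane"),
#' #                      engine = "gromacs")
#' @export
search_index <- function(index, keywords = character(0), repository = NULL,
                         engine = NULL, extension = NULL,
                         date_from = NULL, date_to = NULL,
                         size_min = NULL, size_max = NULL,
                         search_zip_members = TRUE,
                         map = default_engine_map()) {
  stopifnot(inherits(index, "md_index"))
  ds <- index$datasets
  files <- index$files
  if (!search_zip_members) files <- files[!files$from_zip, , drop = FALSE]
  for (d in c(date_from, date_to)) {
    if (!is.null(d) && is.na(normalize_date(d))) {
      stop("malformed date bound: ", d, call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(ds))
  if (!is.null(repository)) keep <- keep & ds$repository %in% repository
  if (!is.null(date_from)) {
    keep <- keep & !is.na(ds$publication_date) &
      ds$publication_date >= normalize_date(date_from)
  }
  if (!is.null(date_to)) {
    keep <- keep & !is.na(ds$publication_date) &
      ds$publication_date <= normalize_date(date_to)
  }
  if (!is.null(size_min)) keep <- keep & ds$total_size_bytes >= size_min
  if (!is.null(size_max)) keep <- keep & ds$total_size_bytes <= size_max
  fkey <- paste(files$repository, files$dataset_id)
  dkey <- paste(ds$repository, ds$dataset_id)
  if (!is.null(engine)) {
    ok <- unique(fkey[assign_engine(files$file_extension, map) %in% engine])
    keep <- keep & dkey %in% ok
  }
  if (!is.null(extension)) {
    ok <- unique(fkey[files$file_extension %in% extension])
    keep <- keep & dkey %in% ok
  }
  keywords <- keywords[nzchar(keywords)]
  score <- integer(nrow(ds))
  if (length(keywords)) {
    names_by_ds <- split(files$file_name, fkey)
    haystack <- vapply(seq_len(nrow(ds)), function(i) {
      tolower(paste(ds$title[i], ds$description[i],
                    paste(names_by_ds[[dkey[i]]] %||% "", collapse = " ")))
    }, character(1L))
    for (kw in unique(tolower(keywords))) {
      score <- score + as.integer(grepl(kw, haystack, fixed = TRUE))
    }
    keep <- keep & score > 0L
  }
  out <- data.frame(
    repository = ds$repository, dataset_id = ds$dataset_id, doi = ds$doi,
    title = ds$title, publication_date = ds$publication_date,
    score = score, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  ord <- order(-out$score,
               xtfrm(out$publication_date) * -1,
               out$dataset_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  match_keys <- paste(out$repository, out$dataset_id)
  mf <- files[fkey %in% match_keys, , drop = FALSE]
  if (!is.null(extension)) {
    mf <- mf[mf$file_extension %in% extension, , drop = FALSE]
  }
  if (!is.null(engine)) {
    mf <- mf[assign_engine(mf$file_extension, map) %in% engine, , drop = FALSE]
  }
  rownames(mf) <- NULL
  out$n_matching_files <- as.integer(
    table(factor(paste(mf$repository, mf$dataset_id),
                 levels = match_keys)))
  attr(out, "files") <- mf
  class(out) <- c("md_search_results", class(out))
  out
}

#' @export
print.md_search_results <- function(x, ...) {
  cat(nrow(x), "matching dataset(s),",
      nrow(attr(x, "files")), "matching file row(s)\n")
  print(as.data.frame(utils::head(x, 20L)))
  if (nrow(x) > 20L) cat("...\n")
  invisible(x)
}

dataset_url <- function(repository, dataset_id, doi) {
  ifelse(!is.na(doi) & doi != "", paste0("https://doi.org/", doi),
         paste0(c(zenodo = "https://zenodo.org/record/",
                  figshare = "https://figshare.com/articles/",
                  osf = "https://osf.io/")[repository], dataset_id))
}

#' Export search results as TSV
#'
#' One row per matching file, with dataset provenance columns (DOI and a
#' link back to the original repository) so hits remain traceable.
#' Embedded tabs and newlines in free-text fields are replaced by spaces,
#' preserving the column structure; output is UTF-8 with a header row.
#'
#' @param results an `md_search_results` object from [search_index()].
#' @param index the searched `md_index` (for titles and DOIs).
#' @param target output file path.
#' @return number of data rows written, invisibly.
#' @export
export_tsv <- function(results, index, target) {
  files <- attr(results, "files")
  ds <- index$datasets
  dkey <- paste(ds$repository, ds$dataset_id)
  i <- match(paste(files$repository, files$dataset_id), dkey)
  out <- data.frame(
    repository = files$repository,
    dataset_id = files$dataset_id,
    doi = ds$doi[i],
    dataset_url = dataset_url(files$repository, files$dataset_id, ds$doi[i]),
    title = sanitize_cell(ds$title[i]),
    publication_date = ds$publication_date[i],
    file_name = sanitize_cell(files$file_name),
    file_extension = files$file_extension,
    size_bytes = files$size_bytes,
    from_zip = files$from_zip,
    origin_zip = sanitize_cell(files$origin_zip),
    stringsAsFactors = FALSE)
  con <- file(target, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(nrow(out))
}

#' Persist an index snapshot as Parquet tables
#'
#' Writes `datasets.parquet` and `files.parquet` (column names as in the
#' in-memory tables) plus a small `snapshot.json` with the harvest date.
#'
#' @param index an `md_index`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [load_snapshot()]
#' @export
save_snapshot <- function(index, path) {
  stopifnot(inherits(index, "md_index"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  arrow::write_parquet(index$datasets, file.path(path, "datasets.parquet"))
  arrow::write_parquet(index$files, file.path(path, "files.parquet"))
  jsonlite::write_json(list(harvest_date = index$harvest_date),
                       file.path(path, "snapshot.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load an index snapshot from Parquet tables
#'
#' Reads `datasets.parquet` and `files.parquet` from a directory, checks
#' the required columns are present (a schema error names any missing
#' ones), and preserves unknown extra columns.
#'
#' @param path snapshot directory.
#' @return an `md_index`.
#' @export
load_snapshot <- function(path) {
  dpath <- file.path(path, "datasets.parquet")
  fpath <- file.path(path, "files.parquet")
  for (p in c(dpath, fpath)) {
    if (!file.exists(p)) stop("snapshot table missing: ", p, call. = FALSE)
  }
  datasets <- as.data.frame(arrow::read_parquet(dpath))
  files <- as.data.frame(arrow::read_parquet(fpath))
  miss_d <- setdiff(DATASET_COLUMNS, names(datasets))
  miss_f <- setdiff(FILE_COLUMNS, names(files))
  if (length(miss_d) || length(miss_f)) {
    stop("snapshot schema error: missing column(s) ",
         paste(c(miss_d, miss_f), collapse = ", "), call. = FALSE)
  }
  meta <- file.path(path, "snapshot.json")
  harvest_date <- if (file.exists(meta)) {
    jsonlite::read_json(meta)$harvest_date %||% NA_character_
  } else {
    NA_character_
  }
  extra_d <- datasets[, setdiff(names(datasets), DATASET_COLUMNS), drop = FALSE]
  extra_f <- files[, setdiff(names(files), FILE_COLUMNS), drop = FALSE]
  out <- md_index(datasets, files, harvest_date)
  if (ncol(extra_d)) out$datasets <- cbind(out$datasets, extra_d)
  if (ncol(extra_f)) out$files <- cbind(out$files, extra_f)
  out
}
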