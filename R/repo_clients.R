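#' Search one repository for datasets matching a typed query
#'
#' Runs the repository's search endpoint for one (file type, keyword) query
#' and traverses every result page. The page documents have the recorded
#' shape `{"hits": [ids...], "n_pages": N}`; a missing page document counts
#' as zero hits. Duplicate ids across pages are removed, keeping first-seen
#' order.
#'
#' @param repo one of `"zenodo"`, `"figshare"`, `"osf"`.
#' @param query one row of [build_queries()] output (or a list with
#'   `file_type` and `keyword`).
#' @param transport a transport from [fixture_transport()] or
#'   [http_transport()].
#' @return character vector of dataset ids (possibly empty).
#' @export
search_datasets <- function(repo, query, transport) {
  check_repo(repo)
  ids <- character(0)
  page <- 1L
  repeat {
    doc <- tryCatch(
      transport$search(repo, query$file_type, query$keyword, page),
      error = function(e) {
        if (inherits(e, "mdscout_harvest_error")) stop(e)
        stop(harvest_error(repo, sprintf("search %s/%s page %d",
                                         query$file_type, query$keyword, page),
                           conditionMessage(e)))
      })
    if (is.null(doc)) break
    hits <- as.character(unlist(doc$hits %||% list()))
    n_pages <- doc$n_pages %||% page
    if (!is.numeric(n_pages) || length(n_pages) != 1L) {
      stop(parse_error(sprintf("malformed search page for %s/%s page %d",
                               repo, query$file_type, page)))
    }
    ids <- c(ids, hits)
    if (page >= n_pages) break
    page <- page + 1L
  }
  unique(ids)
}

#' Fetch one dataset's metadata and file listing
#'
#' Returns the latest version of the dataset: when the record carries
#' several versions, the one with the newest publication date wins, ties
#' broken by the lexicographically greater version tag. Publication dates
#' are normalized to ISO-8601 at ingest.
#'
#' @inheritParams search_datasets
#' @param dataset_id repository-local dataset identifier.
#' @return list of class `raw_dataset_record`: `repository`, `dataset_id`,
#'   `version_tag`, `doi`, `title`, `description`, `publication_date`,
#'   `license` and `file_entries` (data.frame `name`, `size_bytes`,
#'   `download_url`).
#' @export
fetch_dataset <- function(repo, dataset_id, transport) {
  check_repo(repo)
  doc <- transport$dataset(repo, dataset_id)
  if (!is.null(doc$versions) && length(doc$versions)) {
    dates <- normalize_date(vapply(doc$versions, function(v)
      scalar_chr(v$publication_date), character(1L)))
    tags <- vapply(doc$versions, function(v) scalar_chr(v$version_tag),
                   character(1L))
    ord <- order(dates, tags)
    pick <- ord[length(ord)]
    if (length(ord) > 1L && dates[ord[length(ord) - 1L]] == dates[pick] &&
        tags[ord[length(ord) - 1L]] != tags[pick]) {
      message("version tie for ", repo, "/", dataset_id,
              ": keeping version_tag ", tags[pick])
    }
    base <- doc
    base$versions <- NULL
    doc <- utils::modifyList(base, doc$versions[[pick]])
  }
  entries <- doc$files %||% doc$file_entries %||% list()
  file_entries <- if (length(entries)) {
    do.call(rbind, lapply(entries, function(f) {
      data.frame(name = scalar_chr(f$name),
                 size_bytes = as.numeric(f$size_bytes %||% NA_real_),
                 download_url = scalar_chr(f$download_url),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(name = character(0), size_bytes = numeric(0),
               download_url = character(0), stringsAsFactors = FALSE)
  }
  if (any(!is.na(file_entries$size_bytes) & file_entries$size_bytes < 0)) {
    stop(parse_error(sprintf("negative file size in %s/%s", repo, dataset_id)))
  }
  structure(list(
    repository = repo,
    dataset_id = as.character(dataset_id),
    version_tag = scalar_chr(doc$version_tag),
    doi = scalar_chr(doc$doi),
    title = scalar_chr(doc$title),
    description = scalar_chr(doc$description),
    publication_date = normalize_date(scalar_chr(doc$publication_date)),
    license = scalar_chr(doc$license),
    file_entries = file_entries
  ), class = "raw_dataset_record")
}

#' Parse a repository zip-preview page
#'
#' Zenodo and Figshare expose the member listing of deposited zip archives
#' as HTML (not through their APIs); each repository has its own markup
#' dialect. OSF provides no preview at all, which is reported as a distinct
#' unsupported-preview error. The Zenodo preview is capped at the first
#' 1000 members: a Zenodo listing of 1000 entries is therefore flagged
#' truncated. Either dialect may also declare truncation explicitly with a
#' `data-truncated="true"` attribute on the listing element.
#'
#' @param markup HTML text of the preview page.
#' @param repo `"zenodo"` or `"figshare"`.
#' @return list of class `zip_preview`: `entries` (data.frame `path`,
#'   `size_bytes`) and `truncated` (logical).
#' @export
parse_zip_preview <- function(markup, repo) {
  check_repo(repo)
  if (repo == "osf") {
    stop(structure(
      class = c("mdscout_unsupported_preview", "error", "condition"),
      list(message = "OSF provides no zip preview", call = NULL)))
  }
  doc <- tryCatch(xml2::read_html(markup),
                  error = function(e) stop(parse_error(
                    paste("unparseable zip preview:", conditionMessage(e)))))
  if (repo == "zenodo") {
    table <- xml2::xml_find_first(doc, "//table[contains(@class,'zip-files')]")
    if (inherits(table, "xml_missing")) {
      stop(parse_error("zip preview: no zenodo file table found"))
    }
    rows <- xml2::xml_find_all(table, ".//tr[td]")
    path <- xml2::xml_text(xml2::xml_find_first(rows, "./td[1]"))
    size <- xml2::xml_text(xml2::xml_find_first(rows, "./td[2]"))
    declared <- xml2::xml_attr(table, "data-truncated")
  } else {
    list_el <- xml2::xml_find_first(doc, "//ul[contains(@class,'zip-list')]")
    if (inherits(list_el, "xml_missing")) {
      stop(parse_error("zip preview: no figshare file list found"))
    }
    items <- xml2::xml_find_all(list_el, "./li")
    path <- xml2::xml_text(items)
    size <- xml2::xml_attr(items, "data-size")
    declared <- xml2::xml_attr(list_el, "data-truncated")
  }
  size_bytes <- suppressWarnings(as.numeric(gsub(",", "", trimws(size))))
  entries <- data.frame(path = trimws(path), size_bytes = size_bytes,
                        stringsAsFactors = FALSE)
  entries <- entries[!is.na(entries$path) & entries$path != "", , drop = FALSE]
  rownames(entries) <- NULL
  truncated <- identical(tolower(declared %||% "false"), "true") ||
    (repo == "zenodo" && nrow(entries) >= 1000L)
  structure(list(entries = entries, truncated = truncated),
            class = "zip_preview")
}

#' Download one indexed file into a local cache
#'
#' Plain files are downloaded once and verified against a recorded MD5
#' checksum on later calls (cache hit: no transfer). A file inside a zip
#' archive is obtained by downloading the archive once and extracting only
#' the requested member.
#'
#' @param entry one row of an index `files` table (see [expand()]): needs
#'   `repository`, `dataset_id`, `file_name`, `from_zip`, `origin_zip`,
#'   `download_url`.
#' @param cache_dir local cache directory.
#' @param transport transport used for the transfer.
#' @param index the `md_index` the entry came from; required for zip
#'   members (to locate the archive's download URL).
#' @return local path of the cached file.
#' @export
fetch_file <- function(entry, cache_dir, transport, index = NULL) {
  entry <- as.list(entry)
  dest <- file.path(cache_dir, entry$repository, entry$dataset_id,
                    entry$file_name)
  md5_file <- paste0(dest, ".md5")
  if (file.exists(dest) && file.exists(md5_file)) {
    recorded <- readLines(md5_file, warn = FALSE)[1L]
    actual <- unname(tools::md5sum(dest))
    if (!identical(recorded, actual)) {
      stop("integrity error: checksum mismatch for cached ", dest,
           call. = FALSE)
    }
    return(dest)
  }
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(as.logical(entry$from_zip))) {
    if (is.null(index)) {
      stop("fetching a zip member requires the index to locate the archive",
           call. = FALSE)
    }
    files <- index$files
    zrow <- files[files$repository == entry$repository &
                    files$dataset_id == entry$dataset_id &
                    files$file_name == entry$origin_zip &
                    !files$from_zip, , drop = FALSE]
    if (nrow(zrow) == 0L || is.na(zrow$download_url[1L])) {
      stop("archive ", entry$origin_zip, " has no download URL in the index",
           call. = FALSE)
    }
    zip_local <- fetch_file(zrow[1L, ], cache_dir, transport, index)
    listed <- utils::unzip(zip_local, list = TRUE)$Name
    if (!entry$file_name %in% listed) {
      stop("extraction error: member ", dQuote(entry$file_name),
           " not present in archive ", entry$origin_zip, call. = FALSE)
    }
    utils::unzip(zip_local, files = entry$file_name, exdir = dirname(dest),
                 junkpaths = TRUE)
    extracted <- file.path(dirname(dest), basename(entry$file_name))
    if (extracted != dest) file.rename(extracted, dest)
  } else {
    if (is.null(entry$download_url) || is.na(entry$download_url)) {
      stop("file ", entry$file_name, " has no download URL", call. = FALSE)
    }
    transport$download(entry$download_url, dest)
  }
  writeLines(unname(tools::md5sum(dest)), md5_file)
  dest
}
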