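# Transports decouple the harvesting logic from the network: every
# repository access goes through one of these objects, so the whole
# pipeline runs byte-identically against a recorded/generated fixture tree,
# and live harvesting only swaps the transport.

#' Transport over a recorded or generated fixture tree
#'
#' The fixture layout is one JSON document per (endpoint, page) plus raw
#' HTML zip previews, laid out under one directory per repository:
#' \preformatted{
#'   <dir>/<repo>/search_<ext>_<keyword-slug>_p<page>.json
#'   <dir>/<repo>/dataset_<id>.json
#'   <dir>/<repo>/preview_<id>_<zip-slug>.html
#'   <dir>/<repo>/content/<id>/<file name>     (downloadable bodies)
#' }
#' [gen_corpus()] writes exactly this layout. A missing search page means
#' zero hits; a missing dataset document raises a missing-dataset error,
#' mirroring a live 404.
#'
#' @param dir root of the fixture tree.
#' @return a transport object (list of access functions) of class
#'   `md_transport`.
#' @seealso [search_datasets()], [fetch_dataset()], [gen_corpus()]
#' @export
fixture_transport <- function(dir) {
  force(dir)
  search_path <- function(repo, file_type, keyword, page) {
    file.path(dir, repo, sprintf("search_%s_%s_p%d.json",
                                 file_type, slug(keyword), page))
  }
  structure(list(
    mode = "fixture",
    root = dir,
    search = function(repo, file_type, keyword, page) {
      path <- search_path(repo, file_type, keyword, page)
      if (!file.exists(path)) return(NULL)
      jsonlite::read_json(path, simplifyVector = FALSE)
    },
    dataset = function(repo, dataset_id) {
      path <- file.path(dir, repo, sprintf("dataset_%s.json", dataset_id))
      if (!file.exists(path)) {
        stop(missing_dataset_error(repo, dataset_id))
      }
      jsonlite::read_json(path, simplifyVector = FALSE)
    },
    preview = function(repo, dataset_id, zip_name) {
      path <- file.path(dir, repo, sprintf("preview_%s_%s.html",
                                           dataset_id, slug(zip_name)))
      if (!file.exists(path)) return(NULL)
      paste(readLines(path, warn = FALSE), collapse = "\n")
    },
    download = function(url, dest) {
      src <- sub("^fixture://", "", url)
      if (!grepl("^/", src)) src <- file.path(dir, src)
      if (!file.exists(src)) {
        stop("fixture download source not found: ", url, call. = FALSE)
      }
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      file.copy(src, dest, overwrite = TRUE)
      dest
    }
  ), class = "md_transport")
}

#' Live transport over the repository HTTP APIs
#'
#' Minimal live counterpart of [fixture_transport()]: requests are
#' rate-limited per repository and retried with exponential backoff.
#' Endpoint construction follows the public Zenodo, Figshare and OSF APIs.
#' Not used by the test suite (which is fully offline); provided for real
#' harvests.
#'
#' @param delay_s minimum delay between requests to one repository.
#' @param retries number of attempts per request.
#' @return a transport object of class `md_transport`.
#' @export
http_transport <- function(delay_s = 1, retries = 3L) {
  last_hit <- new.env(parent = emptyenv())
  get_json <- function(repo, url) {
    prev <- last_hit[[repo]] %||% 0
    wait <- delay_s - (as.numeric(Sys.time()) - prev)
    if (wait > 0) Sys.sleep(wait)
    for (attempt in seq_len(retries)) {
      res <- tryCatch({
        txt <- paste(readLines(url, warn = FALSE), collapse = "\n")
        jsonlite::fromJSON(txt, simplifyVector = FALSE)
      }, error = identity)
      last_hit[[repo]] <- as.numeric(Sys.time())
      if (!inherits(res, "error")) return(res)
      if (attempt < retries) Sys.sleep(2^attempt)
    }
    stop(harvest_error(repo, url, conditionMessage(res)))
  }
  search_url <- function(repo, file_type, keyword, page) {
    q <- utils::URLencode(trimws(paste(keyword,
                                       paste0('filetype:"', file_type, '"'))),
                          reserved = TRUE)
    switch(repo,
      zenodo = sprintf("https://zenodo.org/api/records?q=%s&size=100&page=%d", q, page),
      figshare = sprintf("https://api.figshare.com/v2/articles/search?search_for=%s&page=%d", q, page),
      osf = sprintf("https://api.osf.io/v2/search/files/?q=%s&page=%d", q, page)
    )
  }
  structure(list(
    mode = "live",
    search = function(repo, file_type, keyword, page) {
      get_json(repo, search_url(repo, file_type, keyword, page))
    },
    dataset = function(repo, dataset_id) {
      url <- switch(repo,
        zenodo = sprintf("https://zenodo.org/api/records/%s", dataset_id),
        figshare = sprintf("https://api.figshare.com/v2/articles/%s", dataset_id),
        osf = sprintf("https://api.osf.io/v2/nodes/%s/", dataset_id))
      get_json(repo, url)
    },
    preview = function(repo, dataset_id, zip_name) {
      NULL # live preview pages are fetched by URL recorded in the dataset
    },
    download = function(url, dest) {
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      dest
    }
  ), class = "md_transport")
}

harvest_error <- function(repo, what, message) {
  structure(
    class = c("mdscout_harvest_error", "error", "condition"),
    list(message = sprintf("harvest failed [%s] %s: %s", repo, what, message),
         call = NULL, repo = repo, what = what)
  )
}

missing_dataset_error <- function(repo, dataset_id) {
  structure(
    class = c("mdscout_missing_dataset", "mdscout_harvest_error",
              "error", "condition"),
    list(message = sprintf("dataset not found: %s/%s", repo, dataset_id),
         call = NULL, repo = repo, dataset_id = dataset_id)
  )
}

parse_error <- function(message) {
  structure(
    class = c("mdscout_parse_error", "error", "condition"),
    list(message = message, call = NULL)
  )
}
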