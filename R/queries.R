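#' Read a query configuration file
#'
#' The YAML schema mirrors the curated file-type/keyword lists used for
#' harvesting: `file_types` is a list of `{ext, keyword_required}` entries,
#' `keywords` a list of free-text search terms, and the optional
#' `clean_exclude` names file types that do *not* count as MD evidence in
#' the cleaning step (generic archives found via keyword queries).
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return list of class `query_config` with elements `file_types`
#'   (data.frame `ext`, `keyword_required`), `keywords` (character) and
#'   `target_extensions` (character: the file types minus `clean_exclude`).
#' @seealso [build_queries()], [clean_index()]
#' @export
read_query_config <- function(path = system.file("extdata", "query_config.yml",
                                                 package = "mdscout")) {
  cfg <- yaml::read_yaml(path)
  ft <- do.call(rbind, lapply(cfg$file_types, function(e) {
    data.frame(ext = tolower(e$ext),
               keyword_required = isTRUE(e$keyword_required),
               stringsAsFactors = FALSE)
  }))
  keywords <- as.character(unlist(cfg$keywords %||% character(0)))
  exclude <- tolower(as.character(unlist(cfg$clean_exclude %||% character(0))))
  structure(
    list(file_types = ft, keywords = keywords,
         target_extensions = setdiff(ft$ext, exclude)),
    class = "query_config"
  )
}

#' Build the search queries for a harvest
#'
#' One query is emitted per file type when the extension is specific enough
#' to stand alone (`keyword_required = FALSE`, empty keyword), and one per
#' (file type, keyword) pair otherwise. Order follows the configuration.
#'
#' @param config a `query_config` from [read_query_config()], or a list with
#'   the same shape.
#' @return data.frame with columns `file_type`, `keyword`,
#'   `keyword_required`; one row per query.
#' @examples
#' cfg <- read_query_config()
#' head(build_queries(cfg))
#' @export
build_queries <- function(config) {
  ft <- config$file_types
  if (is.null(ft) || nrow(ft) == 0L) {
    stop("query configuration lists no file types", call. = FALSE)
  }
  if (any(is.na(ft$ext) | ft$ext == "")) {
    stop("query configuration contains an empty file type", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(ft)), function(i) {
    if (ft$keyword_required[i]) {
      if (!length(config$keywords)) {
        stop("file type ", dQuote(ft$ext[i]),
             " requires keywords but the configuration lists none",
             call. = FALSE)
      }
      data.frame(file_type = ft$ext[i], keyword = config$keywords,
                 keyword_required = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(file_type = ft$ext[i], keyword = "",
                 keyword_required = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
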