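FILE_COLUMNS <- c("repository", "dataset_id", "file_name", "file_extension",
                  "size_bytes", "from_zip", "origin_zip", "download_url")
DATASET_COLUMNS <- c("repository", "dataset_id", "doi", "title", "description",
                     "publication_date", "license", "version_tag",
                     "n_files", "total_size_bytes", "n_zip_files",
                     "n_files_within_zip")

empty_files_table <- function() {
  data.frame(repository = character(0), dataset_id = character(0),
             file_name = character(0), file_extension = character(0),
             size_bytes = numeric(0), from_zip = logical(0),
             origin_zip = character(0), download_url = character(0),
             stringsAsFactors = FALSE)
}

empty_datasets_table <- function() {
  data.frame(repository = character(0), dataset_id = character(0),
             doi = character(0), title = character(0),
             description = character(0), publication_date = character(0),
             license = character(0), version_tag = character(0),
             n_files = integer(0), total_size_bytes = numeric(0),
             n_zip_files = integer(0), n_files_within_zip = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct an index snapshot
#'
#' An index snapshot is the product of a harvest: one table of datasets and
#' one table of files (plain files and previewed zip members). Invariants
#' are checked: dataset keys `(repository, dataset_id)` are unique, every
#' file row belongs to a dataset row, and the per-dataset aggregates
#' (`n_files`, `n_zip_files`, `n_files_within_zip`, `total_size_bytes`)
#' match the file rows.
#'
#' @param datasets data.frame with the dataset columns (see [expand()]).
#' @param files data.frame with the file columns.
#' @param harvest_date ISO date string of the harvest.
#' @return object of class `md_index`.
#' @export
md_index <- function(datasets, files, harvest_date = format(Sys.Date())) {
  datasets <- datasets[, DATASET_COLUMNS, drop = FALSE]
  files <- files[, FILE_COLUMNS, drop = FALSE]
  key <- paste(datasets$repository, datasets$dataset_id)
  if (anyDuplicated(key)) {
    stop("duplicate (repository, dataset_id) in datasets table", call. = FALSE)
  }
  fkey <- paste(files$repository, files$dataset_id)
  if (!all(fkey %in% key)) {
    stop("file rows reference datasets absent from the datasets table",
         call. = FALSE)
  }
  if (any(files$from_zip != !is.na(files$origin_zip))) {
    stop("from_zip must be TRUE exactly when origin_zip is present",
         call. = FALSE)
  }
  rownames(datasets) <- NULL
  rownames(files) <- NULL
  structure(list(datasets = datasets, files = files,
                 harvest_date = as.character(harvest_date)),
            class = "md_index")
}

#' @export
print.md_index <- function(x, ...) {
  cat("MD index snapshot (harvested ", x$harvest_date, ")\n", sep = "")
  cat("  datasets: ", nrow(x$datasets), "\n", sep = "")
  cat("  files:    ", sum(!x$files$from_zip), " plain + ",
      sum(x$files$from_zip), " zip members\n", sep = "")
  for (repo in unique(x$datasets$repository)) {
    cat("  - ", repo, ": ", sum(x$datasets$repository == repo),
        " datasets\n", sep = "")
  }
  invisible(x)
}

#' Explore phase: find candidate datasets by typed queries
#'
#' Runs every query against every repository and returns the union of hits.
#' A dataset is identified by `(repository, dataset_id)`; the same id in
#' two repositories is two candidates. Individual query failures abort the
#' harvest with an error carrying the repository and query.
#'
#' @param repos character vector of repository names.
#' @param queries data.frame from [build_queries()].
#' @param transport a transport object.
#' @return data.frame with columns `repository`, `dataset_id` (unique rows,
#'   stable order).
#' @seealso [expand()], [clean_index()]
#' @export
explore <- function(repos, queries, transport) {
  for (r in repos) check_repo(r)
  out <- data.frame(repository = character(0), dataset_id = character(0),
                    stringsAsFactors = FALSE)
  for (repo in repos) {
    for (i in seq_len(nrow(queries))) {
      ids <- search_datasets(repo, queries[i, ], transport)
      if (length(ids)) {
        out <- rbind(out, data.frame(repository = repo, dataset_id = ids,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[!duplicated(paste(out$repository, out$dataset_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand phase: catalogue every file of the candidate datasets
#'
#' For each candidate the full file listing is indexed: every plain file
#' becomes a file row, and every zip archive additionally contributes one
#' row per previewed member (`from_zip = TRUE`). File sizes come from the
#' API metadata / preview, never from downloads — the expand phase
#' transfers no data files. Datasets whose fetch fails are skipped with a
#' warning and the harvest continues. `total_size_bytes` sums plain files
#' only (zip member sizes would double-count the archive bytes).
#'
#' @param candidates data.frame from [explore()].
#' @param transport a transport object.
#' @param harvest_date ISO date recorded in the snapshot.
#' @return an [md_index()] snapshot.
#' @export
expand <- function(candidates, transport, harvest_date = format(Sys.Date())) {
  ds_rows <- list()
  file_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    repo <- candidates$repository[i]
    id <- candidates$dataset_id[i]
    rec <- tryCatch(fetch_dataset(repo, id, transport), error = function(e) e)
    if (inherits(rec, "error")) {
      warning("skipping dataset ", repo, "/", id, ": ",
              conditionMessage(rec), call. = FALSE)
      next
    }
    fe <- rec$file_entries
    plain <- if (nrow(fe)) {
      data.frame(repository = repo, dataset_id = rec$dataset_id,
                 file_name = fe$name, file_extension = file_extension(fe$name),
                 size_bytes = fe$size_bytes, from_zip = FALSE,
                 origin_zip = NA_character_, download_url = fe$download_url,
                 stringsAsFactors = FALSE)
    } else {
      empty_files_table()
    }
    members <- empty_files_table()
    zips <- plain$file_name[plain$file_extension == "zip"]
    for (zip_name in zips) {
      markup <- transport$preview(repo, rec$dataset_id, zip_name)
      if (is.null(markup)) next
      preview <- tryCatch(parse_zip_preview(markup, repo), error = function(e) e)
      if (inherits(preview, "error")) {
        message("zip preview unreadable for ", repo, "/", rec$dataset_id,
                "/", zip_name, "; indexing archive without content")
        next
      }
      if (preview$truncated) {
        message("zip preview truncated for ", repo, "/", rec$dataset_id,
                "/", zip_name, " (", nrow(preview$entries), " members listed)")
      }
      if (nrow(preview$entries)) {
        members <- rbind(members, data.frame(
          repository = repo, dataset_id = rec$dataset_id,
          file_name = preview$entries$path,
          file_extension = file_extension(preview$entries$path),
          size_bytes = preview$entries$size_bytes, from_zip = TRUE,
          origin_zip = zip_name, download_url = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
    rows <- rbind(plain, members)
    ds_rows[[length(ds_rows) + 1L]] <- data.frame(
      repository = repo, dataset_id = rec$dataset_id,
      doi = rec$doi, title = rec$title, description = rec$description,
      publication_date = rec$publication_date, license = rec$license,
      version_tag = rec$version_tag,
      n_files = nrow(plain),
      total_size_bytes = sum(plain$size_bytes, na.rm = TRUE),
      n_zip_files = length(zips),
      n_files_within_zip = nrow(members),
      stringsAsFactors = FALSE)
    file_rows[[length(file_rows) + 1L]] <- rows
  }
  datasets <- if (length(ds_rows)) do.call(rbind, ds_rows) else empty_datasets_table()
  files <- if (length(file_rows)) do.call(rbind, file_rows) else empty_files_table()
  md_index(datasets, files, harvest_date)
}

#' Cleaning step: drop datasets with no MD-typed file
#'
#' The expand phase deliberately keeps whole datasets, so keyword hits on
#' generic archives can pull in false positives. Cleaning retains a dataset
#' only if at least one of its files — plain or inside a previewed zip —
#' has an extension from the curated target list; all rows of removed
#' datasets are dropped. Idempotent, and never adds datasets.
#'
#' @param index an `md_index`.
#' @param target_extensions character vector of MD-evidence extensions,
#'   typically `read_query_config()$target_extensions`.
#' @return the cleaned `md_index`.
#' @export
clean_index <- function(index, target_extensions) {
  stopifnot(inherits(index, "md_index"))
  files <- index$files
  hit <- files$file_extension %in% target_extensions
  keep_keys <- unique(paste(files$repository, files$dataset_id)[hit])
  ds_keys <- paste(index$datasets$repository, index$datasets$dataset_id)
  datasets <- index$datasets[ds_keys %in% keep_keys, , drop = FALSE]
  files <- files[paste(files$repository, files$dataset_id) %in% keep_keys, ,
                 drop = FALSE]
  md_index(datasets, files, index$harvest_date)
}

#' Merge two index snapshots
#'
#' Per `(repository, dataset_id)`, the record from the snapshot with the
#' newer harvest date wins, and its file rows replace the older ones
#' atomically. When harvest dates tie, the record with the
#' lexicographically greater version tag is kept (logged).
#'
#' @param a,b `md_index` snapshots.
#' @return merged `md_index` carrying the newer harvest date.
#' @export
merge_snapshots <- function(a, b) {
  stopifnot(inherits(a, "md_index"), inherits(b, "md_index"))
  newer_first <- if (b$harvest_date >= a$harvest_date) list(b, a) else list(a, b)
  win <- newer_first[[1L]]
  lose <- newer_first[[2L]]
  if (a$harvest_date == b$harvest_date && !identical(a, b)) {
    win_keys <- paste(win$datasets$repository, win$datasets$dataset_id)
    lose_keys <- paste(lose$datasets$repository, lose$datasets$dataset_id)
    both <- intersect(win_keys, lose_keys)
    for (k in both) {
      tw <- win$datasets$version_tag[win_keys == k]
      tl <- lose$datasets$version_tag[lose_keys == k]
      if (!is.na(tl) && (is.na(tw) || tl > tw)) {
        message("harvest-date tie for ", k, ": keeping version_tag ", tl)
        win$datasets[win_keys == k, ] <- lose$datasets[lose_keys == k, ]
        wf <- paste(win$files$repository, win$files$dataset_id) != k
        lf <- paste(lose$files$repository, lose$files$dataset_id) == k
        win$files <- rbind(win$files[wf, , drop = FALSE],
                           lose$files[lf, , drop = FALSE])
      }
    }
  }
  win_keys <- paste(win$datasets$repository, win$datasets$dataset_id)
  lose_keep <- !(paste(lose$datasets$repository, lose$datasets$dataset_id)
                 %in% win_keys)
  datasets <- rbind(win$datasets, lose$datasets[lose_keep, , drop = FALSE])
  lose_file_keep <- !(paste(lose$files$repository, lose$files$dataset_id)
                      %in% win_keys)
  files <- rbind(win$files, lose$files[lose_file_keep, , drop = FALSE])
  md_index(datasets, files, max(a$harvest_date, b$harvest_date))
}
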