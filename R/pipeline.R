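#' Download and annotate the Gromacs content files of an index
#'
#' The indexing phases never transfer data files; this step does. Every
#' plain (non-zip-member) `.gro` file is fetched, parsed and categorized
#' into a composition profile, and every plain `.mdp` file is fetched,
#' parsed and annotated. Files that fail to download or parse are skipped
#' with a warning and reported in the result.
#'
#' @param index an `md_index` (typically after [clean_index()]).
#' @param transport transport to fetch file bodies with.
#' @param cache_dir local download cache.
#' @param dictionary residue dictionary for [categorize_residues()].
#' @return list with `profiles` (list of `composition_profile`),
#'   `gro_files` (data.frame of the parsed rows plus `n_atoms`),
#'   `mdp_annotations` (data.frame: file provenance + [annotate_mdp()]
#'   columns), `n_failed`.
#' @export
annotate_index <- function(index, transport, cache_dir = tempfile("mdcache"),
                           dictionary = read_residue_dictionary()) {
  stopifnot(inherits(index, "md_index"))
  files <- index$files
  plain <- files[!files$from_zip, , drop = FALSE]
  n_failed <- 0L

  gro_rows <- plain[plain$file_extension == "gro", , drop = FALSE]
  profiles <- list()
  gro_meta <- list()
  for (i in seq_len(nrow(gro_rows))) {
    res <- tryCatch({
      path <- fetch_file(gro_rows[i, ], cache_dir, transport, index)
      sys <- parse_gro(path)
      list(profile = categorize_residues(sys, dictionary),
           n_atoms = sys$n_atoms)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", gro_rows$file_name[i], ": ",
              conditionMessage(res), call. = FALSE)
      n_failed <- n_failed + 1L
      next
    }
    profiles[[length(profiles) + 1L]] <- res$profile
    meta <- gro_rows[i, c("repository", "dataset_id", "file_name")]
    meta$n_atoms <- res$n_atoms
    meta$group_label <- res$profile$group_label
    gro_meta[[length(gro_meta) + 1L]] <- meta
  }

  mdp_rows <- plain[plain$file_extension == "mdp", , drop = FALSE]
  ann <- list()
  for (i in seq_len(nrow(mdp_rows))) {
    res <- tryCatch({
      path <- fetch_file(mdp_rows[i, ], cache_dir, transport, index)
      annotate_mdp(parse_mdp(path))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", mdp_rows$file_name[i], ": ",
              conditionMessage(res), call. = FALSE)
      n_failed <- n_failed + 1L
      next
    }
    ann[[length(ann) + 1L]] <-
      cbind(mdp_rows[i, c("repository", "dataset_id", "file_name")], res)
  }

  gro_files <- if (length(gro_meta)) do.call(rbind, gro_meta) else
    data.frame(repository = character(0), dataset_id = character(0),
               file_name = character(0), n_atoms = integer(0),
               group_label = character(0), stringsAsFactors = FALSE)
  mdp_annotations <- if (length(ann)) do.call(rbind, ann) else
    cbind(data.frame(repository = character(0), dataset_id = character(0),
                     file_name = character(0), stringsAsFactors = FALSE),
          annotate_mdp(parse_mdp(character(0)))[0, ])
  rownames(gro_files) <- NULL
  rownames(mdp_annotations) <- NULL
  list(profiles = profiles, gro_files = gro_files,
       mdp_annotations = mdp_annotations, n_failed = n_failed)
}

#' Run the full harvest pipeline against a transport
#'
#' Convenience wrapper chaining [build_queries()], [explore()], [expand()]
#' and [clean_index()].
#'
#' @param repos repositories to harvest.
#' @param transport a transport object.
#' @param query_config a `query_config`.
#' @param harvest_date ISO date recorded in the snapshot.
#' @return cleaned `md_index`.
#' @export
harvest_index <- function(repos, transport,
                          query_config = read_query_config(),
                          harvest_date = format(Sys.Date())) {
  queries <- build_queries(query_config)
  candidates <- explore(repos, queries, transport)
  index <- expand(candidates, transport, harvest_date)
  clean_index(index, query_config$target_extensions)
}
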