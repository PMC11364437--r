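# Shared helpers: tiny fixture builders used across test files.

# Generate a corpus in a fresh temp dir; returns list(dir, manifest, spec).
make_corpus <- function(seed = 1L, spec = corpus_spec(seed = seed)) {
  dir <- tempfile(sprintf("corpus%d_", seed))
  manifest <- gen_corpus(spec, dir)
  list(dir = dir, manifest = manifest, spec = spec)
}

# Run the whole pipeline over a fixture tree.
run_pipeline <- function(dir, repos = c("zenodo", "figshare", "osf"),
                         cfg = read_query_config()) {
  transport <- fixture_transport(dir)
  index <- suppressMessages(harvest_index(repos, transport, cfg))
  annotations <- annotate_index(index, transport,
                                cache_dir = tempfile("cache"))
  list(index = index, annotations = annotations)
}

sorted_keys <- function(df) sort(paste(df$repository, df$dataset_id))

# Hand-written dataset fixture document (for version / error cases).
write_dataset_json <- function(dir, repo, id, doc) {
  dir.create(file.path(dir, repo), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(doc, file.path(dir, repo,
                                      sprintf("dataset_%s.json", id)),
                       auto_unbox = TRUE, digits = NA)
}

write_search_json <- function(dir, repo, ext, keyword, page, hits, n_pages) {
  dir.create(file.path(dir, repo), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(hits = as.list(hits), n_pages = n_pages),
    file.path(dir, repo, sprintf("search_%s_%s_p%d.json", ext,
                                 mdscout:::slug(keyword), page)),
    auto_unbox = TRUE)
}

zenodo_preview_html <- function(paths, sizes, truncated_attr = NULL) {
  attr_txt <- if (is.null(truncated_attr)) "" else
    sprintf(" data-truncated=\"%s\"", truncated_attr)
  paste0("<html><body><table class=\"zip-files\"", attr_txt, ">",
         "<tr><th>Name</th><th>Size</th></tr>",
         paste(sprintf("<tr><td>%s</td><td>%d</td></tr>", paths,
                       as.integer(sizes)), collapse = ""),
         "</table></body></html>")
}

figshare_preview_html <- function(paths, sizes) {
  paste0("<html><body><ul class=\"zip-list\">",
         paste(sprintf("<li data-size=\"%d\">%s</li>", as.integer(sizes),
                       paths), collapse = ""),
         "</ul></body></html>")
}
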