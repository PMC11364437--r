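test_that("explore unions query hits per repository without cross-repo merging", {
  dir <- tempfile()
  write_search_json(dir, "zenodo", "gro", "", 1, c("A", "B"), 1)
  write_search_json(dir, "zenodo", "mdp", "", 1, c("B", "C"), 1)
  write_search_json(dir, "figshare", "gro", "", 1, c("A"), 1)
  tr <- fixture_transport(dir)
  queries <- data.frame(file_type = c("gro", "mdp"), keyword = "",
                        stringsAsFactors = FALSE)
  out <- explore(c("zenodo", "figshare"), queries, tr)
  expect_equal(sorted_keys(out),
               sort(c("zenodo A", "zenodo B", "zenodo C", "figshare A")))
  none <- explore("osf", queries, tr)
  expect_equal(nrow(none), 0L)
})

test_that("expand catalogues plain files and previewed zip members with aggregates", {
  dir <- tempfile()
  write_dataset_json(dir, "zenodo", "d1", list(
    dataset_id = "d1", version_tag = "v1", doi = "10.1/d1", title = "t",
    description = "", publication_date = "2021-01-01", license = "CC-BY",
    files = list(
      list(name = "run.mdp", size_bytes = 100, download_url = "fixture://u"),
      list(name = "traj.zip", size_bytes = 5000, download_url = "fixture://v"))))
  html <- zenodo_preview_html(c("a.gro", "b.log"), c(40, 60))
  writeLines(html, file.path(dir, "zenodo",
                             sprintf("preview_d1_%s.html",
                                     mdscout:::slug("traj.zip"))))
  idx <- expand(data.frame(repository = "zenodo", dataset_id = "d1"),
                fixture_transport(dir))
  expect_equal(sum(!idx$files$from_zip), 2L)
  expect_equal(sum(idx$files$from_zip), 2L)
  ds <- idx$datasets
  expect_equal(ds$n_files, 2L)
  expect_equal(ds$n_zip_files, 1L)
  expect_equal(ds$n_files_within_zip, 2L)
  expect_equal(ds$total_size_bytes, 5100) # plain files only
  expect_equal(idx$files$origin_zip[idx$files$from_zip],
               c("traj.zip", "traj.zip"))
})

test_that("expand skips unfetchable datasets and keeps harvesting", {
  dir <- tempfile()
  write_dataset_json(dir, "osf", "ok", list(
    dataset_id = "ok", version_tag = "v1", doi = NA, title = "t",
    description = "", publication_date = "2020-02-02", license = NA,
    files = list(list(name = "x.gro", size_bytes = 1,
                      download_url = "fixture://w"))))
  cands <- data.frame(repository = "osf", dataset_id = c("ok", "gone"))
  expect_warning(idx <- expand(cands, fixture_transport(dir)),
                 "skipping dataset osf/gone")
  expect_equal(idx$datasets$dataset_id, "ok")
})

test_that("cleaning keeps datasets by shared file type, is monotone and idempotent", {
  mk_files <- function(id, names, from_zip = FALSE) {
    data.frame(repository = "zenodo", dataset_id = id, file_name = names,
               file_extension = file_extension(names),
               size_bytes = 1, from_zip = from_zip,
               origin_zip = ifelse(from_zip, "a.zip", NA_character_),
               download_url = NA_character_, stringsAsFactors = FALSE)
  }
  mk_ds <- function(id, files) {
    data.frame(repository = "zenodo", dataset_id = id, doi = NA, title = id,
               description = "", publication_date = "2020-01-01",
               license = NA, version_tag = "v1",
               n_files = sum(!files$from_zip),
               total_size_bytes = sum(files$size_bytes[!files$from_zip]),
               n_zip_files = sum(files$file_extension == "zip" & !files$from_zip),
               n_files_within_zip = sum(files$from_zip),
               stringsAsFactors = FALSE)
  }
  f1 <- rbind(mk_files("junkzip", "a.zip"),
              mk_files("junkzip", c("x.docx", "y.png"), from_zip = TRUE))
  f2 <- rbind(mk_files("onegro", c("one.gro", paste0("f", 1:50, ".txt"))))
  files <- rbind(f1, f2)
  datasets <- rbind(mk_ds("junkzip", f1), mk_ds("onegro", f2))
  idx <- md_index(datasets, files)
  cleaned <- clean_index(idx, c("gro", "mdp", "xtc"))
  expect_equal(cleaned$datasets$dataset_id, "onegro")
  expect_equal(nrow(cleaned$files), 51L) # all files of the kept dataset stay
  # idempotence and monotonicity
  expect_identical(clean_index(cleaned, c("gro", "mdp", "xtc")), cleaned)
  expect_lte(nrow(cleaned$datasets), nrow(idx$datasets))
  # a zip member with a target type also rescues its dataset
  f3 <- rbind(mk_files("zippedgro", "b.zip"),
              mk_files("zippedgro", "inner/sys.gro", from_zip = TRUE))
  idx3 <- md_index(rbind(datasets, mk_ds("zippedgro", f3)), rbind(files, f3))
  expect_true("zippedgro" %in%
                clean_index(idx3, c("gro"))$datasets$dataset_id)
  # empty index passes through
  empty <- clean_index(md_index(datasets[0, ], files[0, ]), "gro")
  expect_equal(nrow(empty$datasets), 0L)
})

test_that("snapshot merging keeps the newer harvest per dataset and is idempotent", {
  mk <- function(id, title, date) {
    files <- data.frame(repository = "zenodo", dataset_id = id,
                        file_name = paste0(title, ".gro"),
                        file_extension = "gro", size_bytes = 1,
                        from_zip = FALSE, origin_zip = NA_character_,
                        download_url = NA_character_, stringsAsFactors = FALSE)
    datasets <- data.frame(repository = "zenodo", dataset_id = id, doi = NA,
                           title = title, description = "",
                           publication_date = "2020-01-01", license = NA,
                           version_tag = "v1", n_files = 1L,
                           total_size_bytes = 1, n_zip_files = 0L,
                           n_files_within_zip = 0L, stringsAsFactors = FALSE)
    md_index(datasets, files, date)
  }
  a <- mk("d1", "old", "2023-01-01")
  b <- mk("d1", "new", "2023-06-01")
  m <- merge_snapshots(a, b)
  expect_equal(m$datasets$title, "new")
  expect_equal(m$files$file_name, "new.gro")
  expect_equal(m$harvest_date, "2023-06-01")
  # disjoint snapshots concatenate
  d <- merge_snapshots(mk("d1", "x", "2023-01-01"), mk("d2", "y", "2023-01-02"))
  expect_equal(sort(d$datasets$dataset_id), c("d1", "d2"))
  # self-merge is identity
  expect_identical(merge_snapshots(a, a), a)
})

test_that("index invariants are enforced at construction", {
  files <- data.frame(repository = "zenodo", dataset_id = "orphan",
                      file_name = "a.gro", file_extension = "gro",
                      size_bytes = 1, from_zip = FALSE,
                      origin_zip = NA_character_,
                      download_url = NA_character_, stringsAsFactors = FALSE)
  expect_error(md_index(mdscout:::empty_datasets_table(), files),
               "reference datasets absent")
  ds <- data.frame(repository = "zenodo", dataset_id = "orphan", doi = NA,
                   title = "t", description = "", publication_date = NA,
                   license = NA, version_tag = NA, n_files = 1L,
                   total_size_bytes = 1, n_zip_files = 0L,
                   n_files_within_zip = 0L, stringsAsFactors = FALSE)
  bad <- files
  bad$from_zip <- TRUE # origin_zip still missing
  expect_error(md_index(ds, bad), "origin_zip")
  expect_error(md_index(rbind(ds, ds), rbind(files, files)),
               "duplicate")
})
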