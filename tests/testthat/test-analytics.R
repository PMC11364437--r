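mk_ann <- function(integrator = "md", dt = 0.002, nsteps = 5e6,
                   tcoupl = "v-rescale", pcoupl = "parrinello-rahman",
                   ref_t = 300) {
  annotate_mdp(parse_mdp(c(
    paste("integrator =", integrator), paste("dt =", dt),
    paste("nsteps =", format(nsteps, scientific = FALSE)),
    paste("tcoupl =", tcoupl), paste("pcoupl =", pcoupl),
    paste("ref_t =", paste(ref_t, collapse = " ")))))
}

test_that("repository summary totals row is the per-repository sum", {
  corp <- make_corpus(seed = 5)
  out <- run_pipeline(corp$dir)
  rs <- repository_summary(out$index)
  tot <- rs[rs$repository == "total", ]
  per <- rs[rs$repository != "total", ]
  for (col in c("n_datasets", "n_files", "n_zip_files", "n_files_within_zip",
                "n_total_files")) {
    expect_equal(tot[[col]], sum(per[[col]]))
  }
  expect_equal(tot$total_size_gb, sum(per$total_size_gb))
  expect_equal(tot$first_dataset_date, min(per$first_dataset_date))
  expect_equal(tot$latest_dataset_date, max(per$latest_dataset_date))
  expect_equal(rs$n_total_files, rs$n_files + rs$n_files_within_zip)
})

test_that("ecdf matches its definition and is permutation invariant", {
  e <- ecdf_table(c(1, 2, 2, 4))
  expect_equal(e$value, c(1, 2, 2, 4))
  expect_equal(e$fraction, c(0.25, 0.75, 0.75, 1.0))
  expect_equal(ecdf_table(7)$fraction, 1.0)
  expect_equal(nrow(ecdf_table(numeric(0))), 0L)
  set.seed(3)
  x <- rexp(50)
  expect_identical(ecdf_table(x), ecdf_table(sample(x)))
  # fraction at the median is at least one half
  expect_gte(e$fraction[which(e$value == stats::median(e$value))[1]], 0.5)
  expect_true(all(diff(e$fraction) >= 0))
})

test_that("extension top-k orders by count with alphabetical tie-break", {
  files <- data.frame(repository = "osf", dataset_id = "d",
                      file_name = c(paste0("a", 1:5, ".dat"),
                                    paste0("b", 1:3, ".txt"), "x", "y"),
                      stringsAsFactors = FALSE)
  files$file_extension <- file_extension(files$file_name)
  files$size_bytes <- 1; files$from_zip <- FALSE
  files$origin_zip <- NA_character_; files$download_url <- NA_character_
  ds <- data.frame(repository = "osf", dataset_id = "d", doi = NA,
                   title = "t", description = "", publication_date = NA,
                   license = NA, version_tag = NA, n_files = 10L,
                   total_size_bytes = 10, n_zip_files = 0L,
                   n_files_within_zip = 0L, stringsAsFactors = FALSE)
  idx <- md_index(ds, files)
  top2 <- extension_top_k(idx, 2)
  expect_equal(top2$extension, c("dat", "txt"))
  expect_equal(top2$count, c(5L, 3L))
  all_of_them <- extension_top_k(idx, 99)
  expect_equal(all_of_them$extension, c("dat", "txt", "none"))
  # ties break alphabetically: none(2) vs a hypothetical tie
  files2 <- files
  files2$file_name <- c(paste0("a", 1:2, ".zz"), paste0("b", 1:2, ".aa"),
                        paste0("c", 1:6, ".bb"))
  files2$file_extension <- file_extension(files2$file_name)
  idx2 <- md_index(ds, files2)
  expect_equal(extension_top_k(idx2, 3)$extension, c("bb", "aa", "zz"))
  # unknown-engine filter keeps only unclaimed extensions
  expect_true(all(extension_top_k(idx, 10, engine_filter = "unknown")$extension
                  %in% c("dat", "txt", "none")))
})

test_that("upset counts aggregate group labels", {
  dict <- read_residue_dictionary()
  mk <- function(resnames, n) {
    categorize_residues(parse_gro(gen_gro(data.frame(
      residue_name = resnames, n_residues = n,
      atoms_per_residue = rep(3, length(resnames))))), dict)
  }
  profiles <- list(mk(c("ALA", "POPC"), c(1, 1)), mk(c("ALA", "POPC"), c(2, 2)),
                   mk("ALA", 1), mk("SOL", 5))
  u <- upset_counts(profiles)
  expect_equal(unname(u["protein+lipid"]), 2L)
  expect_equal(unname(u["protein"]), 1L)
  expect_equal(unname(u["water/ions only"]), 1L)
  expect_equal(sum(u), length(profiles))
})

test_that("coupling flows exclude invalid values and keep the none/none class", {
  ann <- rbind(mk_ann(), mk_ann(),
               mk_ann(tcoupl = "no", pcoupl = "no"),
               mk_ann(tcoupl = "wrongstat"))
  fl <- coupling_flows(ann)
  expect_equal(fl$count[fl$thermostat == "v-rescale" &
                          fl$barostat == "parrinello-rahman"], 2L)
  expect_equal(fl$count[fl$thermostat == "none" & fl$barostat == "none"], 1L)
  expect_equal(sum(fl$count), 3L) # invalid record dropped
  fl_all <- coupling_flows(ann, include_invalid = TRUE)
  expect_equal(sum(fl_all$count), 4L)
  only_invalid <- coupling_flows(mk_ann(tcoupl = "wrongstat"))
  expect_equal(sum(only_invalid$count), 0L)
})

test_that("time distribution separates resolutions, bands and the CG share", {
  ann <- rbind(
    mk_ann(dt = 0.002, nsteps = 10e6),    # AA 20 ns
    mk_ann(dt = 0.002, nsteps = 100e6),   # AA 200 ns
    mk_ann(dt = 0.02, nsteps = 100e6),    # CG 2 us
    mk_ann(dt = 0.02, nsteps = 250e6),    # CG 5 us
    mk_ann(dt = 0.002, nsteps = 1e6),     # AA 2 ns
    mk_ann(integrator = "steep", dt = 0.002, nsteps = 100e6), # excluded
    mk_ann(dt = 0.002, nsteps = 100e3))   # 0.2 ns, excluded
  td <- time_distribution(ann)
  expect_equal(td$n, 5L)
  b <- td$bands
  expect_equal(b$count[b$band == "(1,50]" & b$resolution == "all-atom"], 2L)
  expect_equal(b$count[b$band == "(50,1000]" & b$resolution == "all-atom"], 1L)
  expect_equal(b$count[b$band == "(1000,Inf]" & b$resolution == "coarse-grain"],
               2L)
  expect_equal(td$cg_share_longest_band, 1.0)
  expect_equal(nrow(td$ecdf[["all-atom"]]), 3L)
  expect_equal(max(td$ecdf[["coarse-grain"]]$value), 5000)
  # all-atom only: share of the empty longest band is NaN, not an error
  td_aa <- time_distribution(mk_ann(dt = 0.002, nsteps = 10e6))
  expect_true(is.nan(td_aa$cg_share_longest_band))
})

test_that("temperature histogram bins are left-closed right-open", {
  ann <- rbind(mk_ann(ref_t = 298), mk_ann(ref_t = 300), mk_ann(ref_t = 310),
               mk_ann(ref_t = 400))
  h <- temperature_histogram(ann, bin_width_k = 50)
  expect_equal(h$count[h$bin_start_k == 250], 1L) # 298
  expect_equal(h$count[h$bin_start_k == 300], 2L) # 300 and 310
  expect_equal(h$count[h$bin_start_k == 400], 1L) # 400 sits in [400,450)
  none <- temperature_histogram(mk_ann(ref_t = 300)[0, ], 10)
  expect_equal(nrow(none), 0L)
  many <- temperature_histogram(do.call(rbind, replicate(6, mk_ann(ref_t = 300),
                                                         simplify = FALSE)), 10)
  expect_equal(many$count, 6L)
})

test_that("one representative file per dataset prefers plain lexicographic first", {
  mkf <- function(id, name, from_zip = FALSE) {
    data.frame(repository = "zenodo", dataset_id = id, file_name = name,
               file_extension = file_extension(name), size_bytes = 1,
               from_zip = from_zip,
               origin_zip = ifelse(from_zip, "a.zip", NA_character_),
               download_url = NA_character_, stringsAsFactors = FALSE)
  }
  mkd <- function(id) {
    data.frame(repository = "zenodo", dataset_id = id, doi = NA, title = id,
               description = "", publication_date = NA, license = NA,
               version_tag = NA, n_files = 1L, total_size_bytes = 1,
               n_zip_files = 0L, n_files_within_zip = 0L,
               stringsAsFactors = FALSE)
  }
  files <- rbind(mkf("d1", "traj2.xtc"), mkf("d1", "traj1.xtc"),
                 mkf("d2", "inner/only.xtc", from_zip = TRUE),
                 mkf("d2", "a.zip"),
                 mkf("d3", "nothing.gro"))
  idx <- md_index(rbind(mkd("d1"), mkd("d2"), mkd("d3")), files)
  reps <- sample_one_per_dataset(idx, "xtc")
  expect_equal(nrow(reps), 2L) # d3 has no .xtc
  expect_equal(reps$file_name[reps$dataset_id == "d1"], "traj1.xtc")
  expect_equal(reps$file_name[reps$dataset_id == "d2"], "inner/only.xtc")
})
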