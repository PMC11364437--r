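# Synthetic-corpus backbone: writes a fixture tree that emulates the three
# repositories (search pages, dataset records, zip previews, downloadable
# file bodies) with known ground truth, so the whole pipeline runs offline.
# The manifest of expected results is computed here by direct enumeration
# over the planted draws — it never calls the indexing, parsing or
# analytics code whose output it is later compared against.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Generate a Gromacs .gro coordinate file
#'
#' Writes a valid fixed-column `.gro` file for the given composition:
#' coordinates are drawn uniformly in the box, atom and residue numbering
#' follow the format's 5-digit wrap-around convention.
#'
#' @param composition data.frame with columns `residue_name`, `n_residues`,
#'   `atoms_per_residue`.
#' @param seed optional integer; when given, output is reproducible and
#'   the caller's RNG state is untouched.
#' @param velocities also write velocity columns.
#' @param box box vector lengths in nm.
#' @param title title line text.
#' @return the file content as one string.
#' @examples
#' cat(gen_gro(data.frame(residue_name = "SOL", n_residues = 1,
#'                        atoms_per_residue = 3), seed = 1))
#' @export
gen_gro <- function(composition, seed = NULL, velocities = FALSE,
                    box = c(5, 5, 5), title = "synthetic system") {
  stopifnot(all(c("residue_name", "n_residues", "atoms_per_residue")
                %in% names(composition)))
  if (any(composition$n_residues < 0) || any(composition$atoms_per_residue < 1)) {
    stop("residue counts must be non-negative and atoms per residue positive",
         call. = FALSE)
  }
  with_local_seed(seed, {
    res_id <- rep(seq_len(sum(composition$n_residues)),
                  times = rep(composition$atoms_per_residue,
                              times = composition$n_residues))
    res_name <- rep(rep(composition$residue_name, composition$n_residues),
                    times = rep(composition$atoms_per_residue,
                                times = composition$n_residues))
    atom_in_res <- unlist(lapply(rep(composition$atoms_per_residue,
                                     times = composition$n_residues),
                                 seq_len), use.names = FALSE)
    n_atoms <- length(res_id)
    # coordinates first, velocities after: the two streams stay identical
    # between a velocity file and its velocity-free twin
    xyz <- matrix(stats::runif(3L * n_atoms, 0, min(box)), ncol = 3L,
                  byrow = TRUE)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res_id %% 100000L, res_name,
                     sprintf("A%d", atom_in_res),
                     seq_len(n_atoms) %% 100000L,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    if (velocities && n_atoms > 0L) {
      v <- matrix(stats::runif(3L * n_atoms, -1, 1), ncol = 3L, byrow = TRUE)
      lines <- paste0(lines, sprintf("%8.4f%8.4f%8.4f", v[, 1], v[, 2], v[, 3]))
    }
    if (n_atoms == 0L) lines <- character(0)
    paste(c(title, sprintf("%5d", n_atoms), lines,
            sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), ""),
          collapse = "\n")
  })
}

# Random case / dash-vs-underscore spelling of an .mdp key or value,
# exercising the parser's normalization.
vary_spelling <- function(x, dashes = TRUE) {
  if (dashes && stats::runif(1) < 0.5) x <- gsub("-", "_", x, fixed = TRUE)
  if (stats::runif(1) < 0.3) x <- toupper(x)
  else if (stats::runif(1) < 0.3) {
    substr(x, 1L, 1L) <- toupper(substr(x, 1L, 1L))
  }
  x
}

#' Generate a Gromacs .mdp parameter file
#'
#' Writes `key = value` text for any subset of the mined parameters, with
#' random comment lines, random key case and random `-`/`_` spellings, so
#' parsing must rely on the normalization rules rather than exact strings.
#'
#' @param params named list; recognised names: `integrator`, `dt`,
#'   `nsteps`, `ref_t` (numeric vector), `tcoupl`, `pcoupl`. Anything else
#'   is written as-is.
#' @param seed optional integer (see [gen_gro()]).
#' @return file content as one string.
#' @export
gen_mdp <- function(params = list(), seed = NULL) {
  with_local_seed(seed, {
    lines <- c("; synthetic run parameters")
    emit <- function(key, value) {
      key_out <- vary_spelling(gsub("_", "-", key, fixed = TRUE))
      line <- sprintf("%s = %s", key_out, value)
      if (stats::runif(1) < 0.3) line <- paste0(line, " ; comment")
      lines <<- c(lines, line)
      if (stats::runif(1) < 0.2) lines <<- c(lines, "; filler comment")
    }
    for (key in names(params)) {
      value <- params[[key]]
      if (key %in% c("tcoupl", "pcoupl")) {
        value <- vary_spelling(as.character(value))
      } else if (key == "ref_t") {
        value <- paste(format(value, trim = TRUE, scientific = FALSE),
                       collapse = " ")
      } else {
        value <- format(value, trim = TRUE, scientific = FALSE)
      }
      emit(key, value)
    }
    paste(c(lines, ""), collapse = "\n")
  })
}

#' Generate an uncompressed .xtc trajectory
#'
#' Writes valid big-endian XDR frames on the plain-float branch of the
#' format, which Gromacs uses for systems of at most 9 atoms. Larger
#' systems use the compressed branch, which this generator does not
#' produce (reading it is covered against a reference toolchain instead).
#'
#' @param n_atoms number of atoms (0 to 9).
#' @param times numeric vector of frame times in ps (length = frame count).
#' @param seed optional integer (see [gen_gro()]).
#' @param truncate_bytes drop this many bytes from the end, emulating an
#'   interrupted upload.
#' @return raw vector with the file bytes.
#' @examples
#' read_xtc_info(gen_xtc(3, times = c(0, 10, 20)))
#' @export
gen_xtc <- function(n_atoms, times, seed = NULL, truncate_bytes = 0L) {
  if (n_atoms > 9L) {
    stop("gen_xtc writes the uncompressed branch only (n_atoms <= 9)",
         call. = FALSE)
  }
  with_local_seed(seed, {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    for (i in seq_along(times)) {
      writeBin(c(1995L, as.integer(n_atoms), i - 1L), con, size = 4L,
               endian = "big")
      writeBin(as.numeric(times[i]), con, size = 4L, endian = "big")
      writeBin(as.numeric(c(5, 0, 0, 0, 5, 0, 0, 0, 5)), con, size = 4L,
               endian = "big")
      writeBin(as.integer(n_atoms), con, size = 4L, endian = "big")
      if (n_atoms > 0L) {
        writeBin(stats::runif(3L * n_atoms, 0, 5), con, size = 4L,
                 endian = "big")
      }
    }
    bytes <- rawConnectionValue(con)
    if (truncate_bytes > 0L) {
      bytes <- bytes[seq_len(max(length(bytes) - truncate_bytes, 0L))]
    }
    bytes
  })
}

# ---------------------------------------------------------------------------
# Corpus generation

# Composition templates planted into synthetic .gro files. `categories`
# lists the non-water categories present (drives the expected group label);
# residues lists (name, atoms_per_residue) rows whose residue counts are
# drawn at generation time.
COMPOSITION_TEMPLATES <- list(
  water_only = list(categories = character(0), water = TRUE,
                    residues = data.frame(residue_name = "SOL",
                                          atoms_per_residue = 3)),
  protein = list(categories = "protein", water = TRUE,
                 residues = data.frame(residue_name = c("ALA", "GLY", "SOL", "NA"),
                                       atoms_per_residue = c(5, 4, 3, 1))),
  protein_lipid = list(categories = c("protein", "lipid"), water = TRUE,
                       residues = data.frame(residue_name = c("LEU", "POPC", "SOL"),
                                             atoms_per_residue = c(8, 52, 3))),
  lipid = list(categories = "lipid", water = TRUE,
               residues = data.frame(residue_name = c("DPPC", "W"),
                                     atoms_per_residue = c(12, 1))),
  protein_nucleic = list(categories = c("protein", "nucleic"), water = TRUE,
                         residues = data.frame(residue_name = c("LYS", "DA", "DT", "SOL"),
                                               atoms_per_residue = c(9, 21, 20, 3))),
  protein_glucid = list(categories = c("protein", "glucid"), water = TRUE,
                        residues = data.frame(residue_name = c("SER", "NAG", "SOL"),
                                              atoms_per_residue = c(6, 14, 3))),
  other = list(categories = "other", water = FALSE,
               residues = data.frame(residue_name = c("XYZ", "QQQ"),
                                     atoms_per_residue = c(7, 4)))
)

composition_label_from_template <- function(tpl) {
  if (length(tpl$categories)) {
    cats <- RESIDUE_CATEGORIES[RESIDUE_CATEGORIES %in% tpl$categories]
    paste(cats, collapse = "+")
  } else if (tpl$water) {
    "water/ions only"
  } else {
    "other"
  }
}

# Canonical coupling values drawn for planted .mdp files; "absent" means
# the key is not written, "invalid" writes a value the Gromacs
# documentation does not list.
THERMOSTAT_DRAWS <- c("v-rescale", "berendsen", "nose-hoover", "no",
                      "absent", "invalid")
THERMOSTAT_PROBS <- c(0.45, 0.15, 0.12, 0.10, 0.13, 0.05)
BAROSTAT_DRAWS <- c("parrinello-rahman", "berendsen", "c-rescale", "no",
                    "absent", "invalid")
BAROSTAT_PROBS <- c(0.40, 0.15, 0.08, 0.14, 0.18, 0.05)

#' Specification of a synthetic repository corpus
#'
#' Collects the knobs of [gen_corpus()] with defaults that mirror the
#' statistical structure of real deposits: a mixture of MD engines,
#' all-atom and coarse-grain time-step regimes, reference temperatures
#' peaked at 298-310 K with minor mass between 100 and 800 K, and
#' zip-heavy datasets holding roughly seven times more files inside
#' archives than directly.
#'
#' @param seed integer; the same seed yields a byte-identical corpus.
#' @param n_relevant,n_irrelevant named integer vectors (per repository):
#'   number of genuinely MD-related datasets and of planted false
#'   positives (datasets a keyword query hits whose files — including zip
#'   contents — are all non-MD).
#' @param zip_member_factor mean number of zip members per plain file in
#'   zip-bearing datasets. Together with `p_zip` (and OSF archives never
#'   being previewed) the defaults put the corpus-wide ratio of indexed
#'   zip members to plain files at roughly seven, the zip-heaviness
#'   observed in real deposits.
#' @param p_zip probability that an MD dataset deposits a zip archive.
#' @param dt_pool,dt_probs time-step pool (ps) and mixture weights for
#'   planted `.mdp` files; `NA` plants a file without `dt`.
#' @param temperature_pool,temperature_probs headline-temperature pool (K)
#'   and weights; `NA` plants a file without `ref_t`.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(seed = 1L,
                        n_relevant = c(zenodo = 3L, figshare = 2L, osf = 2L),
                        n_irrelevant = c(zenodo = 1L, figshare = 1L, osf = 0L),
                        zip_member_factor = 12,
                        p_zip = 0.7,
                        dt_pool = c(0.001, 0.002, 0.004, 0.01, 0.02, 0.03, NA),
                        dt_probs = c(0.08, 0.38, 0.16, 0.08, 0.18, 0.06, 0.06),
                        temperature_pool = c(100, 150, 200, 250, 298, 300,
                                             303, 310, 323, 400, 600, 800, NA),
                        temperature_probs = c(0.02, 0.02, 0.02, 0.03, 0.25,
                                              0.25, 0.08, 0.15, 0.03, 0.02,
                                              0.01, 0.02, 0.10)) {
  repos <- union(names(n_relevant), names(n_irrelevant))
  for (r in repos) check_repo(r)
  stopifnot(length(dt_pool) == length(dt_probs),
            length(temperature_pool) == length(temperature_probs),
            zip_member_factor >= 0, p_zip >= 0, p_zip <= 1)
  structure(list(seed = as.integer(seed), n_relevant = n_relevant,
                 n_irrelevant = n_irrelevant,
                 zip_member_factor = zip_member_factor, p_zip = p_zip,
                 dt_pool = dt_pool, dt_probs = dt_probs,
                 temperature_pool = temperature_pool,
                 temperature_probs = temperature_probs),
            class = "corpus_spec")
}

draw <- function(pool, probs) {
  pool[sample.int(length(pool), 1L, prob = probs)]
}

# One planted .mdp parameter draw; returns both the file params and the
# annotation truth derived by direct rule application.
draw_mdp_truth <- function(spec) {
  integrator <- draw(c("md", "sd", "steep", "cg"), c(0.62, 0.13, 0.2, 0.05))
  dt <- draw(spec$dt_pool, spec$dt_probs)
  time_target_ns <- draw(c(0.1, 0.5, 2, 10, 50, 200, 800, 2000, 5000),
                         c(0.12, 0.1, 0.13, 0.2, 0.15, 0.1, 0.08, 0.07, 0.05))
  nsteps <- if (is.na(dt)) {
    draw(c(NA, 50000), c(0.5, 0.5))
  } else {
    round(time_target_ns * 1000 / dt)
  }
  temp <- draw(spec$temperature_pool, spec$temperature_probs)
  n_groups <- draw(1:2, c(0.7, 0.3))
  tcoupl <- draw(THERMOSTAT_DRAWS, THERMOSTAT_PROBS)
  pcoupl <- draw(BAROSTAT_DRAWS, BAROSTAT_PROBS)
  params <- list(integrator = integrator)
  if (!is.na(dt)) params$dt <- dt
  if (!is.na(nsteps)) params$nsteps <- nsteps
  if (!is.na(temp)) params$ref_t <- rep(temp, n_groups)
  if (tcoupl == "invalid") params$tcoupl <- "bogus-stat"
  else if (tcoupl != "absent") params$tcoupl <- tcoupl
  if (pcoupl == "invalid") params$pcoupl <- "bogus-baro"
  else if (pcoupl != "absent") params$pcoupl <- pcoupl
  time_ns <- if (is.na(dt) || is.na(nsteps)) NA_real_ else dt * nsteps / 1000
  list(
    params = params,
    truth = data.frame(
      integrator = integrator,
      dt_ps = dt,
      simulation_time_ns = time_ns,
      resolution = if (is.na(dt)) "unknown"
                   else if (dt >= 0.01) "coarse-grain" else "all-atom",
      thermostat = switch(tcoupl, absent = "none", no = "none", tcoupl),
      barostat = switch(pcoupl, absent = "none", no = "none", pcoupl),
      temperature_k = temp,
      is_production = integrator %in% c("md", "sd") &&
        !is.na(time_ns) && time_ns > 1,
      stringsAsFactors = FALSE)
  )
}

JUNK_EXTENSIONS <- c("docx", "png", "csv", "pptx", "jpg", "md5")
UNKNOWN_MD_EXTENSIONS <- c("pdb", "xyz", "txt", "dat", "out", "xvg", "none",
                           "tiff")
EXTRA_MD_EXTENSIONS <- c("top", "itp", "tpr", "trr", "edr", "ndx", "log",
                         "psf", "dcd", "prmtop", "parm7", "cms")

random_text_file <- function(n_lines = NULL) {
  if (is.null(n_lines)) n_lines <- sample.int(20L, 1L)
  paste(replicate(n_lines, paste(sample(letters, 8L, replace = TRUE),
                                 collapse = "")), collapse = "\n")
}

file_name_for <- function(stem, ext) {
  if (ext == "none") stem else paste0(stem, ".", ext)
}

#' Generate a synthetic repository corpus with its ground-truth manifest
#'
#' Writes the fixture tree [fixture_transport()] reads — per-repository
#' search pages (paginated, 3 hits per page), dataset records, zip preview
#' pages in each repository's HTML dialect (none for OSF, which has no
#' preview), real STORED zip archives, and downloadable `.gro`, `.mdp`,
#' `.log` and `.xtc` file bodies with planted content. The returned
#' manifest holds the expected value of every downstream summary, computed
#' here by direct enumeration over the planted truth; it is also written
#' to `manifest.json` next to the tree.
#'
#' @param spec a [corpus_spec()].
#' @param dir output directory (created; must be empty or absent).
#' @param query_config the query configuration the corpus is built for;
#'   search pages are written for exactly these queries.
#' @return the manifest, invisibly: a list with elements `relevant`,
#'   `removed_by_clean` (data.frames repository/dataset_id), `table1`
#'   (per-repository expected summary), `engine_counts`,
#'   `extension_counts`, `composition_labels`, `mdp_truth` (data.frame),
#'   `coupling_pairs`, `time_bands`, `cg_share_longest_band`,
#'   `temperature_bins_10k`, `n_gro_plain`, `n_mdp_plain`.
#' @export
gen_corpus <- function(spec, dir, query_config = read_query_config()) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE, no.. = TRUE))) {
    stop("corpus output directory is not empty: ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  repos <- union(names(spec$n_relevant), names(spec$n_irrelevant))
  queries <- build_queries(query_config)
  keywords <- query_config$keywords

  set.seed(spec$seed)
  datasets <- list()   # planted truth, one entry per dataset
  counter <- 0L

  for (repo in repos) {
    dir.create(file.path(dir, repo), recursive = TRUE, showWarnings = FALSE)
    n_rel <- spec$n_relevant[[repo]] %||% 0L
    n_irr <- spec$n_irrelevant[[repo]] %||% 0L
    for (i in seq_len(n_rel + n_irr)) {
      relevant <- i <= n_rel
      counter <- counter + 1L
      id <- sprintf("ds%04d", counter)
      content_dir <- file.path(dir, repo, "content", id)
      dir.create(content_dir, recursive = TRUE, showWarnings = FALSE)
      matched_keywords <- sample(keywords, sample.int(3L, 1L))
      plain <- list()  # name, ext, size, has_content
      add_plain <- function(name, ext, content = NULL, bytes = NULL) {
        path <- file.path(content_dir, name)
        dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
        if (!is.null(bytes)) {
          writeBin(bytes, path)
        } else {
          writeLines(content %||% random_text_file(), path, sep = "\n")
        }
        plain[[length(plain) + 1L]] <<- list(name = name, ext = ext,
                                             size = file.size(path))
      }
      gro_truth <- list()
      mdp_truth <- list()

      if (relevant) {
        n_gro <- sample.int(2L, 1L)
        for (g in seq_len(n_gro)) {
          tpl_name <- sample(names(COMPOSITION_TEMPLATES), 1L)
          tpl <- COMPOSITION_TEMPLATES[[tpl_name]]
          comp <- tpl$residues
          comp$n_residues <- sample.int(5L, nrow(comp), replace = TRUE)
          add_plain(sprintf("system%d.gro", g), "gro",
                    content = gen_gro(comp))
          gro_truth[[g]] <- list(
            label = composition_label_from_template(tpl),
            n_atoms = sum(comp$n_residues * comp$atoms_per_residue))
        }
        n_mdp <- sample.int(3L, 1L)
        for (m in seq_len(n_mdp)) {
          dr <- draw_mdp_truth(spec)
          add_plain(sprintf("run%d.mdp", m), "mdp",
                    content = gen_mdp(dr$params))
          mdp_truth[[m]] <- dr$truth
        }
        if (stats::runif(1) < 0.5) {
          add_plain("traj.xtc", "xtc",
                    bytes = gen_xtc(sample.int(9L, 1L),
                                    times = seq(0, by = 10,
                                                length.out = sample.int(6L, 1L))))
        }
        if (stats::runif(1) < 0.5) {
          add_plain("prod.log", "log", content = paste0(
            "Log file opened\nGROMACS version:    2021.",
            sample.int(5L, 1L), "\nCommand line:\n  gmx mdrun -deffnm prod\n"))
        }
        n_extra <- sample.int(3L, 1L)
        for (e in seq_len(n_extra)) {
          ext <- sample(c(EXTRA_MD_EXTENSIONS, UNKNOWN_MD_EXTENSIONS), 1L)
          add_plain(file_name_for(sprintf("extra%d", e), ext), ext)
        }
      } else {
        for (e in seq_len(sample.int(3L, 1L))) {
          ext <- sample(JUNK_EXTENSIONS, 1L)
          add_plain(file_name_for(sprintf("misc%d", e), ext), ext)
        }
      }

      # zip archive: always for irrelevant datasets (they are found through
      # keyword-gated archive queries), with probability p_zip otherwise
      zip_members <- NULL
      has_zip <- if (relevant) stats::runif(1) < spec$p_zip else TRUE
      if (has_zip) {
        n_members <- max(1L, stats::rpois(1L, spec$zip_member_factor *
                                            (length(plain) + 1L)))
        member_ext_pool <- if (relevant) {
          c(EXTRA_MD_EXTENSIONS, UNKNOWN_MD_EXTENSIONS, JUNK_EXTENSIONS,
            "gro", "mdp", "xtc")
        } else {
          JUNK_EXTENSIONS
        }
        exts <- sample(member_ext_pool, n_members, replace = TRUE)
        members <- stats::setNames(
          lapply(seq_len(n_members), function(j) random_text_file(3L)),
          vapply(seq_len(n_members), function(j)
            file_name_for(sprintf("inner/part%03d", j), exts[j]),
            character(1L)))
        zip_path <- file.path(content_dir, "archive.zip")
        write_stored_zip(members, zip_path)
        zip_members <- data.frame(
          path = names(members), ext = exts,
          size = vapply(members, function(m) nchar(m, type = "bytes") ,
                        numeric(1L)),
          stringsAsFactors = FALSE)
        plain[[length(plain) + 1L]] <- list(name = "archive.zip", ext = "zip",
                                            size = file.size(zip_path))
        if (repo != "osf") {
          write_preview_fixture(
            file.path(dir, repo,
                      sprintf("preview_%s_%s.html", id, slug("archive.zip"))),
            repo, zip_members)
        }
      }

      pub_date <- format(as.Date("2014-01-01") +
                           sample.int(3300L, 1L))
      datasets[[length(datasets) + 1L]] <- list(
        repository = repo, dataset_id = id, relevant = relevant,
        matched_keywords = matched_keywords,
        publication_date = pub_date,
        doi = sprintf("10.5072/%s.%s", repo, id),
        title = if (relevant)
          sprintf("Simulation dataset %s (%s)", id, matched_keywords[1L])
        else sprintf("Survey data %s (%s)", id, matched_keywords[1L]),
        plain = do.call(rbind, lapply(plain, function(p)
          data.frame(name = p$name, ext = p$ext, size = p$size,
                     stringsAsFactors = FALSE))),
        zip_members = zip_members,
        gro_truth = gro_truth,
        mdp_truth = if (length(mdp_truth)) do.call(rbind, mdp_truth) else NULL)

      write_dataset_fixture(dir, datasets[[length(datasets)]])
    }
  }

  write_search_fixtures(dir, datasets, queries)
  manifest <- build_manifest(datasets)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

write_dataset_fixture <- function(dir, ds) {
  files <- lapply(seq_len(nrow(ds$plain)), function(i) {
    list(name = ds$plain$name[i],
         size_bytes = ds$plain$size[i],
         download_url = sprintf("fixture://%s/content/%s/%s", ds$repository,
                                ds$dataset_id, ds$plain$name[i]))
  })
  doc <- list(
    dataset_id = ds$dataset_id,
    version_tag = "v1",
    doi = ds$doi,
    title = ds$title,
    description = paste("Deposited files for project", ds$dataset_id, "-",
                        paste(ds$matched_keywords, collapse = "; ")),
    publication_date = ds$publication_date,
    license = "CC-BY-4.0",
    files = files)
  jsonlite::write_json(
    doc, file.path(dir, ds$repository,
                   sprintf("dataset_%s.json", ds$dataset_id)),
    auto_unbox = TRUE, digits = NA)
}

write_preview_fixture <- function(path, repo, members) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  if (repo == "zenodo") {
    rows <- sprintf("    <tr><td>%s</td><td>%d</td></tr>",
                    esc(members$path), as.integer(members$size))
    html <- c("<html><body>",
              "  <table class=\"zip-files\">",
              "    <tr><th>Name</th><th>Size</th></tr>",
              rows, "  </table>", "</body></html>")
  } else {
    rows <- sprintf("    <li data-size=\"%d\">%s</li>",
                    as.integer(members$size), esc(members$path))
    html <- c("<html><body>", "  <ul class=\"zip-list\">", rows,
              "  </ul>", "</body></html>")
  }
  writeLines(html, path)
}

# A dataset is hit by query (ext, keyword) iff it has a plain file of that
# extension and (keyword empty or among the dataset's matched keywords).
write_search_fixtures <- function(dir, datasets, queries, page_size = 3L) {
  for (repo in unique(vapply(datasets, `[[`, character(1L), "repository"))) {
    in_repo <- Filter(function(d) d$repository == repo, datasets)
    for (q in seq_len(nrow(queries))) {
      ext <- queries$file_type[q]
      kw <- queries$keyword[q]
      hits <- vapply(Filter(function(d) {
        ext %in% d$plain$ext && (kw == "" || kw %in% d$matched_keywords)
      }, in_repo), `[[`, character(1L), "dataset_id")
      if (!length(hits)) next
      n_pages <- ceiling(length(hits) / page_size)
      for (p in seq_len(n_pages)) {
        page_hits <- hits[((p - 1L) * page_size + 1L):min(p * page_size,
                                                          length(hits))]
        jsonlite::write_json(
          list(hits = as.list(page_hits), n_pages = n_pages),
          file.path(dir, repo, sprintf("search_%s_%s_p%d.json",
                                       ext, slug(kw), p)),
          auto_unbox = TRUE)
      }
    }
  }
}

# Expected analytics, enumerated directly over the planted truth.
build_manifest <- function(datasets) {
  rel <- Filter(function(d) d$relevant, datasets)
  irr <- Filter(function(d) !d$relevant, datasets)
  ids <- function(xs) if (length(xs)) data.frame(
    repository = vapply(xs, `[[`, character(1L), "repository"),
    dataset_id = vapply(xs, `[[`, character(1L), "dataset_id"),
    stringsAsFactors = FALSE) else
      data.frame(repository = character(0), dataset_id = character(0))

  # members indexed by the pipeline: zip members except on OSF (no preview)
  indexed_members <- function(d) {
    if (is.null(d$zip_members) || d$repository == "osf") NULL else d$zip_members
  }

  table1 <- lapply(split(rel, vapply(rel, `[[`, character(1L), "repository")),
                   function(group) {
    plain_counts <- vapply(group, function(d) nrow(d$plain), integer(1L))
    member_counts <- vapply(group, function(d) {
      m <- indexed_members(d); if (is.null(m)) 0L else nrow(m)
    }, integer(1L))
    dates <- vapply(group, `[[`, character(1L), "publication_date")
    list(n_datasets = length(group),
         first_dataset_date = min(dates),
         latest_dataset_date = max(dates),
         n_files = sum(plain_counts),
         total_size_bytes = sum(vapply(group, function(d) sum(d$plain$size),
                                       numeric(1L))),
         n_zip_files = sum(vapply(group, function(d)
           sum(d$plain$ext == "zip"), integer(1L))),
         n_files_within_zip = sum(member_counts),
         n_total_files = sum(plain_counts) + sum(member_counts))
  })

  all_ext <- unlist(lapply(rel, function(d) {
    c(d$plain$ext, indexed_members(d)$ext)
  }))
  ext_tab <- table(all_ext)
  engine_map <- default_engine_map()
  eng <- unname(engine_map[all_ext])
  eng[is.na(eng)] <- "unknown"
  engine_counts <- table(factor(eng, levels = c(sort(unique(unname(engine_map))),
                                                "unknown")))

  labels <- unlist(lapply(rel, function(d)
    vapply(d$gro_truth, `[[`, character(1L), "label")))
  label_tab <- if (length(labels)) table(labels) else table(character(0))

  mdp <- do.call(rbind, c(lapply(rel, function(d) d$mdp_truth),
                          list(NULL)))
  coupling <- NULL
  time_bands <- NULL
  cg_share <- NA_real_
  temp_bins <- NULL
  if (!is.null(mdp) && nrow(mdp)) {
    ok <- mdp$thermostat != "invalid" & mdp$barostat != "invalid"
    coupling <- stats::aggregate(list(count = rep(1L, sum(ok))),
                                 by = list(thermostat = mdp$thermostat[ok],
                                           barostat = mdp$barostat[ok]),
                                 FUN = sum)
    prod <- mdp[mdp$is_production, , drop = FALSE]
    breaks <- c(1, 50, 1000, Inf)
    lab <- c("(1,50]", "(50,1000]", "(1000,Inf]")
    band <- cut(prod$simulation_time_ns, breaks = breaks, labels = lab)
    time_bands <- expand.grid(band = lab,
                              resolution = c("all-atom", "coarse-grain"),
                              stringsAsFactors = FALSE)
    time_bands$count <- unname(mapply(function(b, r)
      sum(band == b & prod$resolution == r), time_bands$band,
      time_bands$resolution))
    longest <- band == "(1000,Inf]"
    if (any(longest)) {
      cg_share <- sum(longest & prod$resolution == "coarse-grain") /
        sum(longest)
    }
    temps <- mdp$temperature_k[!is.na(mdp$temperature_k)]
    if (length(temps)) {
      starts <- floor(temps / 10) * 10
      tb <- table(starts)
      temp_bins <- data.frame(bin_start_k = as.numeric(names(tb)),
                              count = as.integer(tb))
      temp_bins <- temp_bins[order(temp_bins$bin_start_k), , drop = FALSE]
      rownames(temp_bins) <- NULL
    }
  }

  list(
    relevant = ids(rel),
    removed_by_clean = ids(irr),
    table1 = table1,
    engine_counts = stats::setNames(as.integer(engine_counts),
                                    names(engine_counts)),
    extension_counts = stats::setNames(as.integer(ext_tab), names(ext_tab)),
    composition_labels = stats::setNames(as.integer(label_tab),
                                         names(label_tab)),
    mdp_truth = mdp,
    coupling_pairs = coupling,
    time_bands = time_bands,
    cg_share_longest_band = cg_share,
    temperature_bins_10k = temp_bins,
    n_gro_plain = sum(unlist(lapply(rel, function(d)
      sum(d$plain$ext == "gro")))),
    n_mdp_plain = sum(unlist(lapply(rel, function(d)
      sum(d$plain$ext == "mdp"))))
  )
}
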