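#' Per-repository summary statistics of an index
#'
#' One row per repository plus a `total` row: number of datasets, first and
#' latest dataset dates, plain file count, total size in GB (decimal,
#' 10^9 bytes), zip archive count, previewed zip member count, and total
#' files (plain + members). The totals row is the column sum (min/max for
#' the dates).
#'
#' @param index an `md_index`.
#' @return data.frame with columns `repository`, `n_datasets`,
#'   `first_dataset_date`, `latest_dataset_date`, `n_files`,
#'   `total_size_gb`, `n_zip_files`, `n_files_within_zip`, `n_total_files`.
#' @export
repository_summary <- function(index) {
  stopifnot(inherits(index, "md_index"))
  ds <- index$datasets
  one_row <- function(repo, sub) {
    data.frame(
      repository = repo,
      n_datasets = nrow(sub),
      first_dataset_date = if (nrow(sub)) min(sub$publication_date, na.rm = TRUE) else NA_character_,
      latest_dataset_date = if (nrow(sub)) max(sub$publication_date, na.rm = TRUE) else NA_character_,
      n_files = sum(sub$n_files),
      total_size_gb = sum(sub$total_size_bytes) / 1e9,
      n_zip_files = sum(sub$n_zip_files),
      n_files_within_zip = sum(sub$n_files_within_zip),
      n_total_files = sum(sub$n_files) + sum(sub$n_files_within_zip),
      stringsAsFactors = FALSE)
  }
  repos <- sort(unique(ds$repository))
  rows <- lapply(repos, function(r) one_row(r, ds[ds$repository == r, , drop = FALSE]))
  rows[[length(rows) + 1L]] <- one_row("total", ds)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of indexed files across MD engines
#'
#' Counts every file row (plain files and zip members alike, by default)
#' under its engine assignment.
#'
#' @param index an `md_index`.
#' @param map extension -> engine lookup (see [assign_engine()]).
#' @param include_zip_members count previewed zip members too (default
#'   `TRUE`).
#' @return named integer vector, engine -> file count.
#' @export
engine_distribution <- function(index, map = default_engine_map(),
                                include_zip_members = TRUE) {
  stopifnot(inherits(index, "md_index"))
  files <- index$files
  if (!include_zip_members) files <- files[!files$from_zip, , drop = FALSE]
  engines <- assign_engine(files$file_extension, map)
  levels <- c(sort(unique(unname(map))), "unknown")
  tab <- table(factor(engines, levels = levels))
  stats::setNames(as.integer(tab), names(tab))
}

#' Most frequent file extensions, optionally within one engine
#'
#' @param index an `md_index`.
#' @param k number of extensions to return.
#' @param engine_filter count only files assigned to this engine (e.g.
#'   `"unknown"` for the files no MD engine claims); `NULL` counts all.
#' @param map extension -> engine lookup.
#' @param include_zip_members count previewed zip members too.
#' @return data.frame `extension`, `count`, sorted by decreasing count,
#'   ties broken alphabetically; the `"none"` bucket (extensionless files)
#'   is an ordinary extension.
#' @export
extension_top_k <- function(index, k, engine_filter = NULL,
                            map = default_engine_map(),
                            include_zip_members = TRUE) {
  stopifnot(inherits(index, "md_index"), k >= 1L)
  files <- index$files
  if (!include_zip_members) files <- files[!files$from_zip, , drop = FALSE]
  ext <- files$file_extension
  if (!is.null(engine_filter)) {
    ext <- ext[assign_engine(ext, map) == engine_filter]
  }
  tab <- table(ext)
  out <- data.frame(extension = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$extension), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Empirical cumulative distribution of a numeric sample
#'
#' Standard ECDF: the fraction at x is the share of observations `<= x`.
#' Returned in long form, one row per observation, sorted — the form used
#' for the cumulative system-size, frame-count and simulation-time curves.
#' Invariant under permutation of the input; `NA`s are dropped.
#'
#' @param values numeric vector.
#' @return data.frame `value` (sorted), `fraction` (non-decreasing, last
#'   value 1 for non-empty input).
#' @examples
#' ecdf_table(c(1, 2, 2, 4))
#' @export
ecdf_table <- function(values) {
  values <- sort(values[!is.na(values)])
  n <- length(values)
  if (n == 0L) {
    return(data.frame(value = numeric(0), fraction = numeric(0)))
  }
  fraction <- vapply(values, function(v) sum(values <= v), numeric(1)) / n
  data.frame(value = values, fraction = fraction)
}

#' Count systems per molecular-composition group
#'
#' The per-group counts behind a composition upset plot: one count per
#' distinct group label (e.g. `"protein+lipid"`, `"water/ions only"`).
#'
#' @param profiles list of `composition_profile` objects
#'   ([categorize_residues()]).
#' @return named integer vector, label -> count, sorted by decreasing
#'   count then label; counts sum to `length(profiles)`.
#' @export
upset_counts <- function(profiles) {
  labels <- vapply(profiles, function(p) p$group_label, character(1L))
  tab <- table(labels)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' Thermostat-barostat flow counts
#'
#' Counts `.mdp` records per (thermostat, barostat) pair — the numbers
#' behind a coupling Sankey diagram. Records whose thermostat or barostat
#' is `"invalid"` (a value the Gromacs documentation does not list) are
#' excluded unless `include_invalid`; `(none, none)` pairs are counted —
#' they are the runs with neither coupling, typically minimizations.
#'
#' @param annotations data.frame with `thermostat` and `barostat` columns
#'   ([annotate_mdp()]).
#' @param include_invalid keep records with invalid coupling values.
#' @return data.frame `thermostat`, `barostat`, `count`.
#' @export
coupling_flows <- function(annotations, include_invalid = FALSE) {
  keep <- if (include_invalid) {
    rep(TRUE, nrow(annotations))
  } else {
    annotations$thermostat != "invalid" & annotations$barostat != "invalid"
  }
  sub <- annotations[keep, , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(thermostat = character(0), barostat = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(sub))),
                          by = list(thermostat = sub$thermostat,
                                    barostat = sub$barostat),
                          FUN = sum)
  agg <- agg[order(-agg$count, agg$thermostat, agg$barostat), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Simulation-time distribution of production runs
#'
#' Restricted to production candidates (md/sd integrator, planned time
#' above 1 ns). Returns the per-resolution cumulative distributions of the
#' planned simulation time, the counts in the reporting bands
#' (1-50 ns, 50 ns-1 us, above 1 us; band edges `(lo, hi]`), and the
#' coarse-grain share of the longest band.
#'
#' @param annotations data.frame from [annotate_mdp()] rows.
#' @param band_edges_ns inner band edges in ns (default `c(50, 1000)`).
#' @return list with `ecdf` (named list of [ecdf_table()] per resolution),
#'   `bands` (data.frame `band`, `resolution`, `count`),
#'   `cg_share_longest_band` (fraction in `[0, 1]`, `NaN` when the longest
#'   band is empty), and `n` (number of production candidates).
#' @export
time_distribution <- function(annotations, band_edges_ns = c(50, 1000)) {
  sub <- annotations[annotations$is_production_candidate, , drop = FALSE]
  breaks <- c(1, band_edges_ns, Inf)
  labels <- paste0("(", breaks[-length(breaks)], ",", breaks[-1L], "]")
  resolutions <- c("all-atom", "coarse-grain")
  ecdfs <- lapply(stats::setNames(resolutions, resolutions), function(r) {
    ecdf_table(sub$simulation_time_ns[sub$resolution == r])
  })
  band <- cut(sub$simulation_time_ns, breaks = breaks, labels = labels,
              right = TRUE)
  bands <- expand.grid(band = labels, resolution = resolutions,
                       stringsAsFactors = FALSE)
  bands$count <- unname(mapply(function(b, r) {
    sum(!is.na(band) & band == b & sub$resolution == r)
  }, bands$band, bands$resolution))
  longest <- bands[bands$band == labels[length(labels)], , drop = FALSE]
  cg_share <- unname(longest$count[longest$resolution == "coarse-grain"] /
    sum(longest$count))
  list(ecdf = ecdfs, bands = bands,
       cg_share_longest_band = cg_share, n = nrow(sub))
}

#' Histogram of headline temperatures
#'
#' Bins are left-closed, right-open (`[lo, hi)`) of the given width,
#' anchored at multiples of the width; records without a temperature are
#' excluded, and empty bins are not listed.
#'
#' @param annotations data.frame with a `temperature_k` column.
#' @param bin_width_k bin width in Kelvin (> 0).
#' @return data.frame `bin_start_k`, `bin_end_k`, `count`.
#' @export
temperature_histogram <- function(annotations, bin_width_k = 10) {
  stopifnot(bin_width_k > 0)
  temps <- annotations$temperature_k
  temps <- temps[!is.na(temps)]
  if (!length(temps)) {
    return(data.frame(bin_start_k = numeric(0), bin_end_k = numeric(0),
                      count = integer(0)))
  }
  start <- floor(temps / bin_width_k) * bin_width_k
  tab <- table(start)
  out <- data.frame(bin_start_k = as.numeric(names(tab)),
                    bin_end_k = as.numeric(names(tab)) + bin_width_k,
                    count = as.integer(tab))
  out <- out[order(out$bin_start_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick one representative file of a given type per dataset
#'
#' For each dataset holding at least one file with the extension, exactly
#' one representative is returned: the lexicographically first plain file
#' path, falling back to the lexicographically first zip-member path when
#' no plain file of that type exists. Used to draw desk-scale samples
#' (e.g. one trajectory per dataset) from an index.
#'
#' @param index an `md_index`.
#' @param extension lowercase extension without dot.
#' @return data.frame of file rows, one per represented dataset.
#' @export
sample_one_per_dataset <- function(index, extension) {
  stopifnot(inherits(index, "md_index"))
  files <- index$files[index$files$file_extension == extension, , drop = FALSE]
  if (!nrow(files)) return(empty_files_table())
  key <- paste(files$repository, files$dataset_id)
  picked <- lapply(split(seq_len(nrow(files)), key), function(idx) {
    sub <- files[idx, , drop = FALSE]
    plain <- sub[!sub$from_zip, , drop = FALSE]
    pool <- if (nrow(plain)) plain else sub
    pool[order(pool$file_name)[1L], , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$repository, out$dataset_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
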