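#' Parse a Gromacs .mdp run-parameter file
#'
#' `.mdp` files are `key = value` text; `;` starts a comment (full line or
#' trailing). Keys are normalized by lowercasing and mapping `-` to `_`
#' (Gromacs treats the two spellings interchangeably), and the last
#' occurrence of a repeated key wins. The parser is total: it never fails on
#' arbitrary text — lines that are neither blank, comment nor `key = value`
#' are skipped and counted in `n_skipped`.
#'
#' Beyond the raw key/value map, the fields mined downstream are pulled out:
#' `integrator`, the time step `dt_ps` (ps), the step count `nsteps`, the
#' reference temperature(s) `ref_t_k` (K, one per coupling group), and the
#' raw thermostat (`tcoupl_raw`) and barostat (`pcoupl_raw`) strings.
#' Non-numeric `dt`/`nsteps` values leave the field `NA`.
#'
#' @param x path to an `.mdp` file, or its content (lines or one string).
#' @return an object of class `mdp_parameters`: list with `raw` (named
#'   character vector in file order), `integrator`, `dt_ps`, `nsteps`,
#'   `ref_t_k` (numeric vector or `NULL`), `tcoupl_raw`, `pcoupl_raw`,
#'   `n_skipped`.
#' @examples
#' p <- parse_mdp(c("integrator = md", "dt = 0.002", "nsteps = 500000",
#'                  "ref-t = 300 300 ; solute solvent", "tcoupl = V-rescale"))
#' p$dt_ps * p$nsteps / 1000  # simulation time in ns
#' @seealso [simulation_time()], [resolution_class()], [normalize_coupling()]
#' @export
parse_mdp <- function(x) {
  lines <- as_lines(x)
  lines <- sub(";.*$", "", lines)
  keep <- grepl("=", lines, fixed = TRUE)
  skipped <- sum(trimws(lines[!keep]) != "")
  keys <- character(0)
  vals <- character(0)
  for (line in lines[keep]) {
    eq <- regexpr("=", line, fixed = TRUE)
    key <- normalize_mdp_key(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    if (key == "") {
      skipped <- skipped + 1L
      next
    }
    keys <- c(keys, key)
    vals <- c(vals, val)
  }
  raw <- stats::setNames(vals, keys)
  last <- function(key) {
    i <- which(keys == key)
    if (length(i)) vals[max(i)] else NA_character_
  }
  dt <- suppressWarnings(as.numeric(last("dt")))
  if (!is.na(dt) && dt <= 0) dt <- NA_real_
  nsteps <- suppressWarnings(as.numeric(last("nsteps")))
  if (!is.na(nsteps) && (nsteps < 0 || nsteps != trunc(nsteps))) nsteps <- NA_real_
  ref_t <- last("ref_t")
  ref_t_k <- if (is.na(ref_t)) NULL else {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ref_t), "\\s+")[[1L]]))
    v <- v[!is.na(v)]
    if (length(v)) v else NULL
  }
  integrator <- last("integrator")
  structure(
    list(
      raw = raw,
      integrator = if (is.na(integrator)) NA_character_ else tolower(integrator),
      dt_ps = dt,
      nsteps = nsteps,
      ref_t_k = ref_t_k,
      tcoupl_raw = last("tcoupl"),
      pcoupl_raw = last("pcoupl"),
      n_skipped = as.integer(skipped)
    ),
    class = "mdp_parameters"
  )
}

normalize_mdp_key <- function(key) {
  gsub("-", "_", tolower(trimws(key)), fixed = TRUE)
}

#' @export
print.mdp_parameters <- function(x, ...) {
  cat("Gromacs run parameters (", length(x$raw), " keys, ",
      x$n_skipped, " lines skipped)\n", sep = "")
  show <- c(integrator = x$integrator, dt_ps = x$dt_ps, nsteps = x$nsteps,
            ref_t_k = paste(x$ref_t_k, collapse = " "),
            tcoupl = x$tcoupl_raw, pcoupl = x$pcoupl_raw)
  for (k in names(show)) {
    if (!is.na(show[[k]]) && show[[k]] != "") cat("  ", k, ": ", show[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' Parse a Gromacs .log run log
#'
#' Extracts the Gromacs version from a `GROMACS version:` banner line and
#' the launch command from a `Command line:` block (or a bare `gmx mdrun ...`
#' line). Fields are `NA` when the pattern is not found — nothing is guessed.
#'
#' @param x path to a `.log` file, or its content.
#' @return list with `gromacs_version` and `command_line` (character or `NA`).
#' @export
parse_log <- function(x) {
  lines <- as_lines(x)
  version <- NA_character_
  command <- NA_character_
  m <- regmatches(lines, regexec("GROMACS version:\\s*(\\S+)", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) version <- m[[hit[1L]]][2L]
  cmd_hdr <- grep("^\\s*Command line:\\s*$", lines)
  if (length(cmd_hdr) && cmd_hdr[1L] < length(lines)) {
    after <- lines[(cmd_hdr[1L] + 1L):length(lines)]
    after <- trimws(after)
    nb <- which(after != "")
    if (length(nb)) command <- after[nb[1L]]
  } else {
    mdrun <- grep("gmx(_mpi|_d)?\\s+mdrun", lines)
    if (length(mdrun)) command <- trimws(lines[mdrun[1L]])
  }
  list(gromacs_version = version, command_line = command)
}
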