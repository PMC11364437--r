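#' Default mapping from file extension to MD engine
#'
#' NAMD and CHARMM share most of their characteristic extensions and are
#' therefore pooled into a single `namd/charmm` engine. Extensions not in
#' the table map to `unknown`.
#'
#' @return named character vector: extension -> engine.
#' @seealso [assign_engine()]
#' @export
default_engine_map <- function() {
  map <- list(
    gromacs = c("gro", "mdp", "xtc", "trr", "tpr", "itp", "top", "edr",
                "ndx", "cpt"),
    amber = c("prmtop", "parm7", "inpcrd", "rst7", "mdcrd", "frcmod"),
    `namd/charmm` = c("psf", "dcd", "prm", "rtf", "str", "coor", "vel", "xsc"),
    desmond = c("cms", "mae")
  )
  stats::setNames(rep(names(map), lengths(map)), unlist(map))
}

#' Assign file extensions to an MD engine
#'
#' @param extension character vector of lowercase extensions (no dot), as
#'   produced by [file_extension()].
#' @param map extension -> engine lookup, by default [default_engine_map()].
#'   A YAML file with `engine: [ext, ...]` entries can be loaded with
#'   [read_engine_map()] to override it.
#' @return character vector over `{gromacs, amber, namd/charmm, desmond,
#'   unknown}`.
#' @examples
#' assign_engine(c("mdp", "psf", "pdb"))
#' @export
assign_engine <- function(extension, map = default_engine_map()) {
  out <- unname(map[as.character(extension)])
  out[is.na(out)] <- "unknown"
  out
}

#' Read an engine-mapping override from YAML
#'
#' @param path YAML file of the form `engine: [ext, ...]`.
#' @return named character vector: extension -> engine.
#' @export
read_engine_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  stats::setNames(rep(names(cfg), lengths(cfg)), tolower(unlist(cfg)))
}

RESIDUE_CATEGORIES <- c("protein", "lipid", "nucleic", "glucid",
                        "water_ions", "other")

#' Read a residue-category dictionary from YAML
#'
#' The dictionary drives the molecular-composition census of coordinate
#' files: each residue name is assigned to one of `protein`, `lipid`,
#' `nucleic`, `glucid` or `water_ions`; anything unlisted is counted as
#' `other`. The packaged default (`residue_categories.yml` in `extdata`)
#' covers the 20 amino acids with common His/terminal variants, common
#' all-atom and Martini lipid names, DNA/RNA residue codes, frequent sugar
#' codes and the usual water/ion names. Where a one-letter code collides
#' between an ion and a ribonucleotide (e.g. `K`), the ion reading wins.
#'
#' @param path YAML file of the form `category: [RESNAME, ...]`; defaults to
#'   the packaged dictionary.
#' @return named character vector: uppercase residue name -> category.
#' @seealso [categorize_residues()]
#' @export
read_residue_dictionary <- function(path = system.file("extdata", "residue_categories.yml",
                                                       package = "mdscout")) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), RESIDUE_CATEGORIES)
  if (length(bad)) {
    stop("unknown residue categories in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(rep(names(cfg), lengths(cfg)),
                  toupper(trimws(as.character(unlist(cfg)))))
}

#' Molecular-composition census of a coordinate file
#'
#' Counts atoms per molecular category by looking each residue name up in
#' the dictionary (case-insensitive, padding stripped); unmatched names
#' count as `other`. The composition group label is the set of non-empty
#' categories excluding water/ions, joined with `+` in the fixed order
#' protein, lipid, nucleic, glucid, other; a system whose only matched
#' categories are water/ions gets the label `"water/ions only"`, and an
#' empty system `"other"`.
#'
#' @param system a `gro_system` from [parse_gro()].
#' @param dictionary residue name -> category lookup, by default the
#'   packaged dictionary ([read_residue_dictionary()]).
#' @return list of class `composition_profile`: `counts` (named integer,
#'   one entry per category, summing to `n_atoms`), `n_atoms`,
#'   `group_label`.
#' @examples
#' sys <- parse_gro(gen_gro(data.frame(
#'   residue_name = c("ALA", "POPC", "SOL"),
#'   n_residues = c(5, 10, 100),
#'   atoms_per_residue = c(5, 50, 3)), seed = 7))
#' categorize_residues(sys)
#' @export
categorize_residues <- function(system, dictionary = read_residue_dictionary()) {
  stopifnot(inherits(system, "gro_system"))
  counts <- stats::setNames(integer(length(RESIDUE_CATEGORIES)),
                            RESIDUE_CATEGORIES)
  res <- toupper(trimws(system$atoms$residue_name))
  if (length(res)) {
    cat <- unname(dictionary[res])
    cat[is.na(cat)] <- "other"
    tab <- table(cat)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(
    list(counts = counts, n_atoms = system$n_atoms,
         group_label = composition_label(counts)),
    class = "composition_profile"
  )
}

# Label rule shared with the corpus generator's manifest.
composition_label <- function(counts) {
  present <- names(counts)[counts > 0L]
  cats <- setdiff(present, "water_ions")
  cats <- RESIDUE_CATEGORIES[RESIDUE_CATEGORIES %in% cats] # fixed order
  if (length(cats)) {
    paste(cats, collapse = "+")
  } else if ("water_ions" %in% present) {
    "water/ions only"
  } else {
    "other"
  }
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Composition (", x$n_atoms, " atoms): ", x$group_label, "\n", sep = "")
  nz <- x$counts[x$counts > 0L]
  if (length(nz)) print(nz)
  invisible(x)
}

#' Planned simulation time of an .mdp file, in nanoseconds
#'
#' The product of the time step (`dt`, ps) and the step count (`nsteps`),
#' converted to ns; `NA` when either is missing. This is the time the run
#' was *set up* for, not evidence that it completed.
#'
#' @param mdp an `mdp_parameters` object from [parse_mdp()].
#' @return numeric scalar (ns) or `NA`.
#' @export
simulation_time <- function(mdp) {
  if (is.na(mdp$dt_ps) || is.na(mdp$nsteps)) return(NA_real_)
  mdp$dt_ps * mdp$nsteps / 1000
}

#' Classify model resolution from the integration time step
#'
#' All-atom force fields need femtosecond time steps, while coarse-grained
#' models (e.g. Martini) integrate stably at 10 fs and above. A time step of
#' at least 0.01 ps (10 fs) is therefore classified `coarse-grain`, anything
#' smaller `all-atom`, and a missing time step `unknown`. The classification
#' depends on `dt` only, never on the step count.
#'
#' @param mdp an `mdp_parameters` object.
#' @return one of `"all-atom"`, `"coarse-grain"`, `"unknown"`.
#' @examples
#' resolution_class(parse_mdp("dt = 0.002")) # all-atom
#' resolution_class(parse_mdp("dt = 0.02"))  # coarse-grain
#' @export
resolution_class <- function(mdp) {
  dt <- mdp$dt_ps
  if (is.na(dt)) "unknown" else if (dt >= 0.01) "coarse-grain" else "all-atom"
}

GROMACS_THERMOSTATS <- c("no", "berendsen", "nose-hoover", "andersen",
                         "andersen-massive", "v-rescale")
GROMACS_BAROSTATS <- c("no", "berendsen", "c-rescale", "parrinello-rahman",
                       "mttk")

#' Canonicalize a thermostat or barostat value
#'
#' Matches the raw `.mdp` value case-insensitively and `-`/`_`-insensitively
#' against the algorithms the Gromacs documentation lists (thermostats:
#' no, berendsen, nose-hoover, andersen, andersen-massive, v-rescale;
#' barostats: no, berendsen, c-rescale, parrinello-rahman, mttk). A missing
#' value or `no` becomes `"none"`; anything else that does not match is
#' `"invalid"` and excluded from flow analytics downstream.
#'
#' @param raw character value (or `NA`) as found in the file.
#' @param kind `"thermostat"` or `"barostat"`.
#' @return canonical string: a documented algorithm name, `"none"` or
#'   `"invalid"`.
#' @examples
#' normalize_coupling("V-rescale", "thermostat")
#' normalize_coupling("Nose_Hoover", "thermostat")
#' normalize_coupling(NA, "barostat")
#' @export
normalize_coupling <- function(raw, kind = c("thermostat", "barostat")) {
  kind <- match.arg(kind)
  canon <- if (kind == "thermostat") GROMACS_THERMOSTATS else GROMACS_BAROSTATS
  if (length(raw) != 1L || is.na(raw) || trimws(raw) == "") return("none")
  key <- gsub("_", "-", tolower(trimws(raw)), fixed = TRUE)
  if (key == "none") return("none")
  hit <- canon[gsub("_", "-", canon, fixed = TRUE) == key]
  if (!length(hit)) return("invalid")
  if (hit == "no") "none" else hit
}

#' Headline temperature of an .mdp file, in Kelvin
#'
#' `ref_t` holds one reference temperature per temperature-coupling group;
#' deposited files overwhelmingly use the same value for every group. The
#' headline temperature reduces the vector to one number — by default the
#' first group's value; `"max"` and `"mean"` are available for sensitivity
#' checks.
#'
#' @param mdp an `mdp_parameters` object.
#' @param rule one of `"first"` (default), `"max"`, `"mean"`.
#' @return numeric scalar (K) or `NA` when `ref_t` is absent.
#' @export
headline_temperature <- function(mdp, rule = c("first", "max", "mean")) {
  rule <- match.arg(rule)
  v <- mdp$ref_t_k
  if (is.null(v) || !length(v)) return(NA_real_)
  switch(rule, first = v[[1L]], max = max(v), mean = mean(v))
}

#' Is an .mdp file a plausible production run?
#'
#' Production molecular-dynamics runs use the `md` or `sd` integrator and a
#' planned simulation time above 1 ns; energy minimizations (`steep`, `cg`,
#' `l-bfgs`) and short equilibration runs fail one of the two conditions.
#'
#' @param mdp an `mdp_parameters` object.
#' @return `TRUE`/`FALSE` (missing fields count as `FALSE`).
#' @export
is_production_candidate <- function(mdp) {
  t_ns <- simulation_time(mdp)
  isTRUE(!is.na(mdp$integrator) && mdp$integrator %in% c("md", "sd") &&
           !is.na(t_ns) && t_ns > 1)
}

#' Annotate one parsed .mdp file
#'
#' Bundles the per-file inferences ([simulation_time()],
#' [resolution_class()], [normalize_coupling()], [headline_temperature()],
#' [is_production_candidate()]) into one row.
#'
#' @param mdp an `mdp_parameters` object.
#' @param temperature_rule passed to [headline_temperature()].
#' @return one-row data.frame with columns `integrator`, `dt_ps`, `nsteps`,
#'   `simulation_time_ns`, `resolution`, `thermostat`, `barostat`,
#'   `temperature_k`, `is_production_candidate`.
#' @export
annotate_mdp <- function(mdp, temperature_rule = "first") {
  data.frame(
    integrator = mdp$integrator,
    dt_ps = mdp$dt_ps,
    nsteps = mdp$nsteps,
    simulation_time_ns = simulation_time(mdp),
    resolution = resolution_class(mdp),
    thermostat = normalize_coupling(mdp$tcoupl_raw, "thermostat"),
    barostat = normalize_coupling(mdp$pcoupl_raw, "barostat"),
    temperature_k = headline_temperature(mdp, temperature_rule),
    is_production_candidate = is_production_candidate(mdp),
    stringsAsFactors = FALSE
  )
}
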