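test_that("parse_gro reads a small water system", {
  txt <- gen_gro(data.frame(residue_name = "SOL", n_residues = 1,
                            atoms_per_residue = 3), seed = 1)
  sys <- parse_gro(txt)
  expect_equal(sys$n_atoms, 3L)
  expect_equal(unique(sys$atoms$residue_name), "SOL")
  expect_equal(nrow(sys$atoms), 3L)
  expect_length(sys$box, 3L)
})

test_that("gro round-trip preserves counts, residue census and coordinates", {
  set.seed(101)
  for (rep in 1:20) {
    n_types <- sample.int(4L, 1L)
    comp <- data.frame(
      residue_name = sample(c("ALA", "SOL", "POPC", "XYZ", "DA", "NAG"),
                            n_types),
      n_residues = sample.int(6L, n_types, replace = TRUE),
      atoms_per_residue = sample.int(8L, n_types, replace = TRUE))
    vel <- rep %% 2 == 0
    txt <- gen_gro(comp, seed = rep, velocities = vel)
    sys <- parse_gro(txt)
    expect_equal(sys$n_atoms, sum(comp$n_residues * comp$atoms_per_residue))
    census <- table(sys$atoms$residue_name)
    expected <- with(comp, tapply(n_residues * atoms_per_residue,
                                  residue_name, sum))
    expect_equal(as.integer(census[names(expected)]),
                 as.integer(expected))
    # coordinates carry the format's 3-decimal precision
    expect_true(all(abs(sys$atoms$x - round(sys$atoms$x, 3)) < 1e-9))
    expect_equal("vx" %in% names(sys$atoms), vel)
  }
})

test_that("velocity columns do not perturb parsed coordinates", {
  comp <- data.frame(residue_name = c("ALA", "SOL"), n_residues = c(2, 4),
                     atoms_per_residue = c(5, 3))
  plain <- parse_gro(gen_gro(comp, seed = 9, velocities = FALSE))
  vel <- parse_gro(gen_gro(comp, seed = 9, velocities = TRUE))
  expect_equal(vel$atoms[c("x", "y", "z")], plain$atoms[c("x", "y", "z")])
  expect_true(all(c("vx", "vy", "vz") %in% names(vel$atoms)))
})

test_that("malformed gro files fail with informative errors", {
  txt <- strsplit(gen_gro(data.frame(residue_name = "SOL", n_residues = 2,
                                     atoms_per_residue = 3), seed = 2),
                  "\n")[[1]]
  expect_error(parse_gro(txt[-4]), "expected 6 atom lines, found 5")
  bad_count <- txt
  bad_count[2] <- "  not_a_number"
  expect_error(parse_gro(bad_count), "atom-count line")
  no_box <- txt[seq_len(length(txt) - 1)]
  expect_error(parse_gro(no_box), "truncated|box")
})

test_that("merged fixed-width columns parse where token splitting would fail", {
  # 5-digit residue number runs into a 5-char residue name: no spaces
  line <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  99999L, "DPPCX", "C1", 12345L, 1.5, -2.25, 10.125)
  expect_false(grepl("^\\s", line))
  sys <- parse_gro(c("t", "    1", line, "   5.0 5.0 5.0"))
  expect_equal(sys$atoms$residue_number, 99999L)
  expect_equal(sys$atoms$residue_name, "DPPCX")
  expect_equal(sys$atoms$x, 1.5)
  expect_equal(sys$atoms$z, 10.125)
})

test_that("zero-atom gro files are valid", {
  txt <- gen_gro(data.frame(residue_name = character(0),
                            n_residues = integer(0),
                            atoms_per_residue = integer(0)), seed = 1)
  sys <- parse_gro(txt)
  expect_equal(sys$n_atoms, 0L)
  expect_equal(nrow(sys$atoms), 0L)
})

test_that("parse_mdp extracts canonical fields under key normalization", {
  p <- parse_mdp(c("dt = 0.002", "nsteps = 500000"))
  expect_equal(p$dt_ps, 0.002)
  expect_equal(p$nsteps, 500000)
  p2 <- parse_mdp("ref-t  = 300 300 ; two groups")
  expect_equal(p2$ref_t_k, c(300, 300))
  p3 <- parse_mdp(c("integrator=md", "integrator=sd"))
  expect_equal(p3$integrator, "sd") # last occurrence wins
  p4 <- parse_mdp(c("; full comment", "Tcoupl = V-rescale",
                    "Pcoupl = Parrinello_Rahman"))
  expect_equal(p4$tcoupl_raw, "V-rescale")
  expect_equal(p4$pcoupl_raw, "Parrinello_Rahman")
})

test_that("parse_mdp is total on arbitrary text and counts skipped lines", {
  set.seed(42)
  for (i in 1:25) {
    junk <- replicate(sample.int(15L, 1L), paste(
      sample(c(letters, " ", "=", ";", "\t", "-", "0", "9"),
             sample.int(30L, 1L), replace = TRUE), collapse = ""))
    expect_no_error(parse_mdp(junk))
  }
  p <- parse_mdp(c("garbage line", "dt = 0.01", "another junk", "", "; ok"))
  expect_equal(p$n_skipped, 2L)
  expect_equal(p$dt_ps, 0.01)
  # non-numeric values leave fields absent
  p2 <- parse_mdp(c("dt = fast", "nsteps = many"))
  expect_true(is.na(p2$dt_ps))
  expect_true(is.na(p2$nsteps))
})

test_that("mdp generator round-trips through the parser", {
  set.seed(7)
  for (i in 1:10) {
    txt <- gen_mdp(list(integrator = "md", dt = 0.004, nsteps = 250000,
                        ref_t = c(310, 310), tcoupl = "nose-hoover",
                        pcoupl = "berendsen"))
    p <- parse_mdp(txt)
    expect_equal(p$integrator, "md")
    expect_equal(p$dt_ps, 0.004)
    expect_equal(p$nsteps, 250000)
    expect_equal(p$ref_t_k, c(310, 310))
    expect_equal(normalize_coupling(p$tcoupl_raw, "thermostat"), "nose-hoover")
    expect_equal(normalize_coupling(p$pcoupl_raw, "barostat"), "berendsen")
  }
  empty <- parse_mdp(gen_mdp(list(), seed = 3))
  expect_true(is.na(empty$integrator) && is.na(empty$dt_ps))
  expect_null(empty$ref_t_k)
})

test_that("parse_log extracts version and command line when present", {
  log <- c("Log file opened on Mon", "GROMACS version:    2021.4",
           "Command line:", "  gmx mdrun -deffnm prod", "")
  info <- parse_log(log)
  expect_equal(info$gromacs_version, "2021.4")
  expect_equal(info$command_line, "gmx mdrun -deffnm prod")
  none <- parse_log("")
  expect_true(is.na(none$gromacs_version) && is.na(none$command_line))
  bare <- parse_log("  gmx mdrun -v -nt 8")
  expect_equal(bare$command_line, "gmx mdrun -v -nt 8")
})

test_that("xtc info recovers atom count, frame count and time range", {
  info <- read_xtc_info(gen_xtc(3, times = seq(0, 40, by = 10), seed = 1))
  expect_equal(info$n_atoms, 3L)
  expect_equal(info$n_frames, 5L)
  expect_equal(info$first_time_ps, 0)
  expect_equal(info$last_time_ps, 40)
  expect_false(info$truncated)
  empty <- read_xtc_info(gen_xtc(3, times = numeric(0)))
  expect_equal(empty$n_frames, 0L)
  expect_true(is.na(empty$first_time_ps))
})

test_that("xtc frame counts add under concatenation", {
  set.seed(11)
  for (i in 1:10) {
    n_atoms <- sample.int(9L, 1L)
    a <- gen_xtc(n_atoms, times = seq_len(sample.int(6L, 1L)))
    b <- gen_xtc(n_atoms, times = seq_len(sample.int(6L, 1L)))
    ia <- read_xtc_info(a); ib <- read_xtc_info(b)
    iab <- read_xtc_info(c(a, b))
    expect_equal(iab$n_frames, ia$n_frames + ib$n_frames)
    expect_equal(iab$n_atoms, n_atoms)
  }
})

test_that("xtc corruption and truncation are reported", {
  bytes <- gen_xtc(4, times = c(0, 10, 20), seed = 5)
  expect_error(read_xtc_info(bytes[-(1:4)]), "not an .xtc")
  cut <- read_xtc_info(gen_xtc(4, times = c(0, 10, 20), seed = 5,
                               truncate_bytes = 7L))
  expect_true(cut$truncated)
  expect_equal(cut$n_frames, 2L) # the partial final frame is not counted
  expect_equal(cut$last_time_ps, 10)
  # frames disagreeing on the atom count are an error
  mixed <- c(gen_xtc(3, 0), gen_xtc(5, 10))
  expect_error(read_xtc_info(mixed), "inconsistent")
})
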