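test_that("engine assignment follows the extension table with an unknown bucket", {
  expect_equal(assign_engine(c("mdp", "gro", "xtc")), rep("gromacs", 3))
  expect_equal(assign_engine("psf"), "namd/charmm")
  expect_equal(assign_engine(c("prmtop", "parm7")), rep("amber", 2))
  expect_equal(assign_engine("cms"), "desmond")
  expect_equal(assign_engine(c("pdb", "none", "xyz")), rep("unknown", 3))
  # user override table
  map <- c(foo = "amber")
  expect_equal(assign_engine(c("foo", "gro"), map), c("amber", "unknown"))
})

test_that("composition census sums to the atom count and labels by category set", {
  dict <- read_residue_dictionary()
  sol <- parse_gro(gen_gro(data.frame(residue_name = "SOL", n_residues = 1,
                                      atoms_per_residue = 3), seed = 1))
  p <- categorize_residues(sol, dict)
  expect_equal(unname(p$counts[["water_ions"]]), 3L)
  expect_equal(p$group_label, "water/ions only")

  mix <- parse_gro(gen_gro(data.frame(
    residue_name = c("ALA", "POPC", "SOL"),
    n_residues = c(1, 1, 100),
    atoms_per_residue = c(5, 50, 3)), seed = 2))
  pm <- categorize_residues(mix, dict)
  expect_equal(pm$group_label, "protein+lipid")
  expect_equal(sum(pm$counts), mix$n_atoms)

  unk <- parse_gro(gen_gro(data.frame(residue_name = "XYZ", n_residues = 4,
                                      atoms_per_residue = 7), seed = 3))
  pu <- categorize_residues(unk, dict)
  expect_equal(unname(pu$counts[["other"]]), 28L)
  expect_equal(pu$group_label, "other")

  empty <- parse_gro(gen_gro(data.frame(residue_name = character(0),
                                        n_residues = integer(0),
                                        atoms_per_residue = integer(0))))
  pe <- categorize_residues(empty, dict)
  expect_equal(sum(pe$counts), 0L)
  expect_equal(pe$group_label, "other")
})

test_that("category counts conserve atoms across random systems", {
  dict <- read_residue_dictionary()
  pool <- c("ALA", "GLY", "POPC", "DA", "NAG", "SOL", "W", "NA", "XYZ", "QQ")
  set.seed(99)
  for (i in 1:200) {
    n <- sample.int(5L, 1L)
    comp <- data.frame(residue_name = sample(pool, n),
                       n_residues = sample.int(4L, n, replace = TRUE),
                       atoms_per_residue = sample.int(6L, n, replace = TRUE))
    sys <- parse_gro(gen_gro(comp))
    p <- categorize_residues(sys, dict)
    expect_identical(sum(p$counts), sys$n_atoms)
  }
})

test_that("simulation time is dt x nsteps in ns", {
  expect_equal(simulation_time(parse_mdp(c("dt = 0.002", "nsteps = 500000"))), 1)
  expect_equal(simulation_time(parse_mdp(c("dt = 0.02", "nsteps = 50000000"))),
               1000)
  expect_true(is.na(simulation_time(parse_mdp("dt = 0.002"))))
})

test_that("resolution classification uses the 10 fs cutoff and only dt", {
  expect_equal(resolution_class(parse_mdp("dt = 0.002")), "all-atom")
  expect_equal(resolution_class(parse_mdp("dt = 0.02")), "coarse-grain")
  expect_equal(resolution_class(parse_mdp("dt = 0.01")), "coarse-grain")
  expect_equal(resolution_class(parse_mdp("dt = 0.0099")), "all-atom")
  expect_equal(resolution_class(parse_mdp("nsteps = 100")), "unknown")
  # metamorphic: varying nsteps never changes the class
  for (nsteps in c(1, 1e4, 1e9)) {
    p <- parse_mdp(c("dt = 0.004", paste("nsteps =", nsteps)))
    expect_equal(resolution_class(p), "all-atom")
  }
})

test_that("coupling values normalize to the documented algorithms", {
  expect_equal(normalize_coupling("V-rescale", "thermostat"), "v-rescale")
  expect_equal(normalize_coupling("Nose_Hoover", "thermostat"), "nose-hoover")
  expect_equal(normalize_coupling(NA, "barostat"), "none")
  expect_equal(normalize_coupling("no", "thermostat"), "none")
  expect_equal(normalize_coupling("Parrinello-rahman", "barostat"),
               "parrinello-rahman")
  expect_equal(normalize_coupling("C_rescale", "barostat"), "c-rescale")
  expect_equal(normalize_coupling("lambda-dynamics", "thermostat"), "invalid")
  # a barostat name is not a valid thermostat
  expect_equal(normalize_coupling("parrinello-rahman", "thermostat"),
               "invalid")
  # idempotence on every canonical output
  for (kind in c("thermostat", "barostat")) {
    canon <- c(mdscout:::GROMACS_THERMOSTATS, "none")
    if (kind == "barostat") canon <- c(mdscout:::GROMACS_BAROSTATS, "none")
    for (v in setdiff(canon, "no")) {
      expect_equal(normalize_coupling(normalize_coupling(v, kind), kind),
                   normalize_coupling(v, kind))
    }
  }
})

test_that("headline temperature reduces ref_t groups by rule", {
  p <- parse_mdp("ref_t = 300 310")
  expect_equal(headline_temperature(p), 300)
  expect_equal(headline_temperature(p, "max"), 310)
  expect_equal(headline_temperature(p, "mean"), 305)
  expect_equal(headline_temperature(parse_mdp("ref-t = 310")), 310)
  expect_true(is.na(headline_temperature(parse_mdp("dt = 0.002"))))
})

test_that("production filter requires md/sd integrator and >1 ns", {
  expect_true(is_production_candidate(
    parse_mdp(c("integrator = md", "dt = 0.002", "nsteps = 25000000"))))
  expect_false(is_production_candidate(
    parse_mdp(c("integrator = steep", "dt = 0.002", "nsteps = 25000000"))))
  expect_false(is_production_candidate(
    parse_mdp(c("integrator = md", "dt = 0.002", "nsteps = 250000")))) # 0.5 ns
  expect_false(is_production_candidate(
    parse_mdp(c("integrator = md", "dt = 0.002", "nsteps = 500000")))) # exactly 1 ns
  expect_true(is_production_candidate(
    parse_mdp(c("integrator = sd", "dt = 0.02", "nsteps = 1000000"))))
})
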