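test_that("unit strings parse to canonical molar scales", {
  expect_equal(parse_conc_unit("uM")$scale, 1e-6)
  expect_identical(parse_conc_unit("uM")$canonical,
                   parse_conc_unit("µM")$canonical)  # micro sign
  expect_identical(parse_conc_unit("uM")$canonical,
                   parse_conc_unit("μM")$canonical)  # Greek mu
  expect_equal(parse_conc_unit("mM")$scale, 1e-3)
  expect_equal(convert_dose(1.8, "mM", "uM"), 1800)
  expect_error(parse_conc_unit("furlongs"), "unknown concentration unit")
})

test_that("plate CSV write/read round-trips and rejects malformed input", {
  p <- gen_viability_plate(100, noise_sd = 2, n_blank = 3, seed = 30)
  f <- tempfile(fileext = ".csv")
  write_plate_csv(p, f)
  p2 <- read_plate_csv(f)
  expect_equal(p2$dose, p$dose)
  expect_equal(p2$od, p$od, tolerance = 1e-12)
  expect_identical(p2$role, p$role)
  expect_identical(attr(p2, "unit"), attr(p, "unit"))

  # od = "NA" reported with its line number
  bad <- readLines(f)
  bad[3] <- sub("^([^,]*,[^,]*,)[^,]*", "\\1NA", bad[3])
  fb <- tempfile(fileext = ".csv"); writeLines(bad, fb)
  expect_error(read_plate_csv(fb), "non-numeric od at line 3")

  # missing column
  noct <- readLines(f)
  noct <- gsub("^dose,", "concentration,", noct[1])
  fm <- tempfile(fileext = ".csv")
  writeLines(c(noct, readLines(f)[-1]), fm)
  expect_error(read_plate_csv(fm), "missing column")

  # mixed units on one plate
  mix <- readLines(f)
  mix[4] <- sub(",uM,", ",mM,", mix[4])
  fx <- tempfile(fileext = ".csv"); writeLines(mix, fx)
  expect_error(read_plate_csv(fx), "one unit")
})

test_that("combination CSV reader validates doses and units", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cell_line,drug_a,dose_a,unit_a,drug_b,dose_b,unit_b",
               "LAN-5,SSZ,1.207,µM,DFMO,1.2,mM",
               "LAN-5,SSZ,58.25,uM,DFMO,1.8,mM"), f)
  df <- read_combination_csv(f)
  expect_equal(df$dose_a, c(1.207, 58.25))
  expect_identical(df$unit_a, c("uM", "uM"))
  writeLines(c("cell_line,drug_a,dose_a,unit_a,drug_b,dose_b,unit_b",
               "LAN-5,SSZ,-3,uM,DFMO,1.2,mM"), f)
  expect_error(read_combination_csv(f), "line 2")
})

test_that("cohort CSV round-trips expression and annotations", {
  co <- gen_cohort(n_per_group = c(a = 10, b = 10), target_r = 0.4, seed = 31)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  co2 <- read_cohort_csv(f)
  expect_equal(co2$expression, co$expression, tolerance = 1e-12)
  expect_identical(co2$annotations$mycn, co$annotations$mycn)
  writeLines(c("sample,clin:mycn", "s1,amplified"), f)
  expect_error(read_cohort_csv(f), "no gene columns")
})

test_that("a handcrafted PDB parses with correct coordinates and chain filter", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY B   7       4.000   5.000   6.000  1.00  0.00           C",
    "END"), f)
  s <- read_structure_pdb(f)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(1, 4))
  sA <- read_structure_pdb(f, chains = "A")
  expect_identical(sA$atoms$chain, "A")
  expect_error(read_structure_pdb(f, chains = "Z"), "no atoms")
})

test_that("PDB reading drops hydrogens and waters and resolves altlocs", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  0.70  0.00           C",
    "ATOM      3  H   ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "HETATM    4  O   HOH A 101       2.000   2.000   2.000  1.00  0.00           O",
    "END"), f)
  s <- read_structure_pdb(f)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 9)  # higher-occupancy altloc wins
})

test_that("synthetic structures and pose ensembles round-trip through PDB", {
  g <- gen_pose_ensemble(n_residues = 20, pocket_size = 4, n_poses = 5, seed = 32)
  fs <- tempfile(fileext = ".pdb")
  write_structure_pdb(g$structure, fs)
  s2 <- read_structure_pdb(fs)
  expect_equal(s2$atoms$x, g$structure$atoms$x, tolerance = 1e-3)
  expect_identical(s2$atoms$resno, g$structure$atoms$resno)
  expect_identical(s2$atoms$chain, g$structure$atoms$chain)
  expect_identical(s2$atoms$resname, g$structure$atoms$resname)
  expect_identical(s2$atoms$elety, g$structure$atoms$elety)
  fp <- tempfile(fileext = ".pdb")
  write_pose_pdb(g$ensemble, fp)
  e2 <- read_pose_pdb(fp)
  expect_equal(length(e2$poses), 5)
  for (k in 1:5)
    expect_equal(e2$poses[[k]], g$ensemble$poses[[k]], tolerance = 1e-3)
  expect_equal(e2$energies, g$ensemble$energies, tolerance = 1e-6)
})

test_that("synergy reports use 3-decimal half-up display and are deterministic", {
  res <- ci_from_doses(c(147.9, 0.893), c(4.0, 6.0), 337.2, 5.79,
                       cell_line = "LAN-5")
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_synergy_report(res, f1); write_synergy_report(res, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_match(lines[1], "^cell_line\tequiv_a\tequiv_b\tci\tclass\tdose_a\tdose_b$")
  expect_match(lines[2], "\t0\\.439\t0\\.691\t1\\.129\tmoderate antagonism\t")
  expect_match(lines[3], "\t0\\.003\t1\\.036\t1\\.039\tadditive\t")
  # empty input: header only
  f3 <- tempfile(fileext = ".tsv")
  write_synergy_report(res[0, ], f3)
  expect_identical(readLines(f3), lines[1])
})

test_that("run configurations validate and read from YAML", {
  cfg <- run_config()
  expect_equal(cfg$contact_cutoff, 3.6)
  expect_equal(cfg$top_k, 50L)
  expect_equal(cfg$effect_level, 50)
  expect_error(run_config(contact_cutoff = -1))
  expect_error(run_config(log_level = "loud"), "quiet, info or debug")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("contact_cutoff: 4.0", "top_k: 25", "seed: 7"), f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$contact_cutoff, 4.0)
  expect_equal(cfg2$top_k, 25L)
  writeLines("cutof: 4.0", f)
  expect_error(read_run_config(f), "unknown config key")
})
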