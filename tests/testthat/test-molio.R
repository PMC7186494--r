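# Structure and pose I/O, charge rules, environment retention

test_that("PDB receptor reading classifies residues and infers elements", {
  pdb <- write_tripeptide_pdb(withr::local_tempfile(fileext = ".pdb"))
  sys <- read_receptor(pdb)
  expect_s3_class(sys, "molsys")
  expect_equal(nrow(sys$atoms), 12L)
  expect_equal(sum(sys$atoms$class == "water"), 1L)
  expect_equal(sys$atoms$resname[sys$atoms$class == "water"], "HOH")
  expect_equal(sys$atoms$element[1:2], c("N", "C"))

  # element column missing: inferred from atom names by the rule table;
  # CA is carbon inside an amino acid but calcium as a one-atom residue
  ion_line <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00            ",
    13, "CA  ", "CA", "A", 91, 9.0, 9.0, 9.0)
  pdb2 <- write_tripeptide_pdb(withr::local_tempfile(fileext = ".pdb"),
                               with_element = FALSE, extra = ion_line)
  sys2 <- read_receptor(pdb2)
  a <- sys2$atoms
  expect_equal(a$element[a$name == "CA" & a$resname == "ASP"], "C")
  expect_equal(a$element[a$resname == "CA"], "Ca")
  expect_equal(a$class[a$resname == "CA"], "ion")
})

test_that("PDB round trip preserves atoms, elements and coordinates", {
  pdb <- write_tripeptide_pdb(withr::local_tempfile(fileext = ".pdb"))
  sys <- read_receptor(pdb)
  out <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_system(sys, out)
  back <- read_receptor(out)
  expect_equal(nrow(back$atoms), nrow(sys$atoms))
  expect_equal(back$atoms$element, sys$atoms$element)
  expect_equal(sys_coords(back), sys_coords(sys), tolerance = 1e-3)
  expect_equal(back$charge, sys$charge)
})

test_that("missing or malformed PDB input raises a parse error", {
  expect_error(read_receptor(file.path(tempdir(), "nope.pdb")), "cannot read")
})

test_that("SDF poses carry bonds, M CHG charges and manifest labels", {
  sdf <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"))
  man <- read_manifest(write_fixture_manifest(
    withr::local_tempfile(fileext = ".tsv"),
    labels = c("ligand", "decoy", "ligand")))
  poses <- read_poses(sdf, man)
  expect_length(poses, 3L)
  expect_equal(vapply(poses, function(p) p$state_id, ""), c("S1", "S2", "S3"))
  expect_equal(vapply(poses, function(p) p$is_ligand, TRUE),
               c(TRUE, FALSE, TRUE))
  # charge block: +1 on atom 1, -1 on atom 3, total 0
  expect_equal(poses[[1]]$system$atoms$charge, c(1L, 0L, -1L))
  expect_equal(poses[[1]]$system$charge, 0L)
  expect_equal(nrow(poses[[1]]$system$bonds), 2L)
})

test_that("a pose record without a manifest row is an error naming the state", {
  sdf <- write_fixture_sdf(withr::local_tempfile(fileext = ".sdf"))
  man <- read_manifest(write_fixture_manifest(
    withr::local_tempfile(fileext = ".tsv"), ids = c("S1", "S2")))
  expect_error(read_poses(sdf, man), "S3")
})

test_that("MOL2 and SDF readers agree on the same molecule", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf_record("M1"), sdf)
  mol2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "M1", " 3 2 1", "SMALL", "USER_CHARGES",
               "@<TRIPOS>ATOM",
               "  1 N1   0.0000  0.0000  0.0000 N.4  1 LIG  1.0000",
               "  2 C1   1.4700  0.0000  0.0000 C.3  1 LIG  0.0000",
               "  3 O1   2.1000  1.3000  0.0000 O.3  1 LIG -1.0000",
               "@<TRIPOS>BOND", " 1 1 2 1", " 2 2 3 1"), mol2)
  man <- read_manifest(write_fixture_manifest(
    withr::local_tempfile(fileext = ".tsv"), ids = "M1"))
  p_sdf <- read_poses(sdf, man)[[1]]
  p_mol2 <- read_poses(mol2, man)[[1]]
  expect_equal(sum(p_mol2$system$atoms$heavy), sum(p_sdf$system$atoms$heavy))
  expect_equal(p_mol2$system$charge, p_sdf$system$charge)
  expect_equal(sys_coords(p_mol2$system), sys_coords(p_sdf$system),
               tolerance = 1e-3)
})

test_that("SDF write/read round trip conserves atoms, charges, coordinates", {
  lib <- make_library(seed = 3, n_ligands = 2, n_decoys = 2)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(lib$poses, sdf)
  man_path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(lib$manifest, man_path)
  back <- read_poses(sdf, read_manifest(man_path))
  expect_length(back, length(lib$poses))
  for (k in seq_along(back)) {
    expect_equal(nrow(back[[k]]$system$atoms), nrow(lib$poses[[k]]$system$atoms))
    expect_equal(back[[k]]$system$charge, lib$poses[[k]]$system$charge)
    expect_equal(sys_coords(back[[k]]$system), sys_coords(lib$poses[[k]]$system),
                 tolerance = 1e-3)
  }
})

test_that("residue charge rules give the expected net charges", {
  pdb <- write_tripeptide_pdb(withr::local_tempfile(fileext = ".pdb"))
  sys <- assign_formal_charges(read_receptor(pdb))
  # Asp -1 + Gly 0 + Lys +1 = 0
  expect_equal(sys$charge, 0L)
  a <- sys$atoms
  expect_equal(sum(a$charge[a$resname == "ASP"]), -1L)
  expect_equal(a$charge[a$name == "NZ"], 1L)
  # idempotent
  expect_identical(assign_formal_charges(sys), sys)
})

test_that("two Glu and one Arg net -1; a calcium ion contributes +2", {
  atoms <- data.frame(
    element = c("C", "C", "C", "Ca"),
    name = c("CB", "CB", "CB", "CA"),
    x = c(0, 5, 10, 15), y = 0, z = 0,
    resname = c("GLU", "GLU", "ARG", "CA"),
    resid = 1:4, chain = "A", charge = 0L,
    class = c("protein", "protein", "protein", "ion"))
  sys <- assign_formal_charges(mol_system(atoms))
  expect_equal(sys$charge, -1L + 2L)
  expect_equal(sys$atoms$charge[4L], 2L)
})

test_that("a nonstandard residue without a charge rule warns and gets 0", {
  atoms <- data.frame(element = "C", name = "C1", x = 0, y = 0, z = 0,
                      resname = "XYZ", resid = 1L, chain = "A",
                      charge = 0L, class = "protein")
  expect_warning(sys <- assign_formal_charges(mol_system(atoms)), "XYZ")
  expect_equal(sys$charge, 0L)
})

test_that("water/ion retention respects the 4 and 8 A boundaries", {
  mk_env <- function(wz, iz) {
    atoms <- data.frame(
      element = c("C", "O", "Ca"),
      name = c("CA", "O", "CA"),
      x = 0, y = 0, z = c(-6, wz, iz),
      resname = c("ALA", "HOH", "CA"),
      resid = 1:3, chain = "A", charge = 0L,
      class = c("protein", "water", "ion"))
    mol_system(atoms)
  }
  ref <- mol_system(data.frame(element = "C", x = 0, y = 0, z = 0,
                               charge = 0L, class = "ligand"))
  kept <- select_environment(mk_env(3.9, 7.9), ref)
  expect_setequal(kept$atoms$class, c("protein", "water", "ion"))
  dropped <- select_environment(mk_env(4.1, 8.1), ref)
  expect_setequal(dropped$atoms$class, "protein")
  # no reference ligand: everything but protein dropped, with a warning
  expect_warning(bare <- select_environment(mk_env(1, 1), NULL), "reference")
  expect_setequal(bare$atoms$class, "protein")
})

test_that("select_environment is monotone in its cutoffs and subsets input", {
  pocket <- make_toy_pocket(seed = 2)
  ref <- make_library(seed = 2, n_ligands = 1, n_decoys = 1)$poses[[1]]$system
  small <- select_environment(pocket, ref, water_cutoff = 2, ion_cutoff = 4)
  big <- select_environment(pocket, ref, water_cutoff = 8, ion_cutoff = 12)
  expect_lte(nrow(small$atoms), nrow(big$atoms))
  expect_lte(nrow(big$atoms), nrow(pocket$atoms))
  key <- function(s) paste(s$atoms$chain, s$atoms$resid, s$atoms$name)
  expect_true(all(key(small) %in% key(big)))
  expect_true(all(key(big) %in% key(pocket)))
})
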