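# Binding-site cluster construction: residue selection, anti-fragmentation,
# hydrogen capping

test_that("residue selection respects the heavy-atom distance boundary", {
  mk_res <- function(resid, z, el = "C") {
    data.frame(element = el, name = "CA", x = 0, y = 0, z = z,
               resname = "ALA", resid = resid, chain = "A",
               charge = 0L, class = "protein")
  }
  probe <- mol_system(data.frame(element = "C", x = 0, y = 0, z = 0,
                                 charge = 0L, class = "ligand"))
  rec <- mol_system(rbind(mk_res(1, 7.9), mk_res(2, 8.1)))
  sel <- residues_within(rec, list(probe), 8.0)
  expect_equal(sel, "A|1")

  # a residue whose only close atom is a hydrogen does not qualify
  rec_h <- mol_system(rbind(mk_res(1, 3.0, el = "H"), mk_res(2, 20)))
  expect_length(residues_within(rec_h, list(probe), 8.0), 0L)

  expect_error(residues_within(rec, list(), 8.0), "empty")
  expect_warning(residues_within(rec, list(probe), 5.0), "below 6")
})

test_that("selection matches the brute-force all-pairs oracle on random pockets", {
  set.seed(101)
  for (rep in 1:20) {
    n_res <- sample(6:14, 1L)
    atoms <- data.frame(
      element = sample(c("C", "N", "O", "H"), n_res * 2L, replace = TRUE),
      name = "X", x = runif(n_res * 2L, -12, 12),
      y = runif(n_res * 2L, -12, 12), z = runif(n_res * 2L, -12, 12),
      resname = "ALA", resid = rep(seq_len(n_res), each = 2L),
      chain = "A", charge = 0L, class = "protein")
    rec <- mol_system(atoms)
    pose <- mol_system(data.frame(
      element = "C", x = runif(2, -4, 4), y = runif(2, -4, 4),
      z = runif(2, -4, 4), charge = 0L, class = "ligand"))
    cutoff <- runif(1, 6, 10)
    expect_setequal(residues_within(rec, list(pose), cutoff),
                    brute_residue_selection(rec, list(pose), cutoff))
  }
})

test_that("selection is monotone in the cutoff", {
  pocket <- make_toy_pocket(seed = 5)
  poses <- make_library(seed = 5, n_ligands = 3, n_decoys = 3)$poses
  s6 <- suppressWarnings(residues_within(pocket, poses, 6))
  s8 <- residues_within(pocket, poses, 8)
  expect_true(all(s6 %in% s8))
})

test_that("defragment bridges short gaps and extends short fragments", {
  # a 12-residue chain receptor
  atoms <- do.call(rbind, lapply(1:12, function(r)
    data.frame(element = "C", name = "CA", x = r * 4, y = 0, z = 0,
               resname = "ALA", resid = r, chain = "A", charge = 0L,
               class = "protein")))
  rec <- mol_system(atoms)
  expect_setequal(defragment(paste0("A|", c(3, 4, 6, 7)), rec, max_gap = 1),
                  paste0("A|", 3:7))
  # singleton extended on the C side
  expect_setequal(defragment("A|10", rec, min_fragment = 2),
                  paste0("A|", 10:11))
  # terminal singleton falls back to the N side
  expect_setequal(defragment("A|12", rec, min_fragment = 2),
                  paste0("A|", 11:12))
  # no gaps, long fragment: identity
  expect_setequal(defragment(paste0("A|", 2:5), rec), paste0("A|", 2:5))
  # output always contains input
  sel <- paste0("A|", c(1, 5, 9))
  expect_true(all(sel %in% defragment(sel, rec)))
})

test_that("defragment snaps a boundary inside an annotated helix", {
  atoms <- do.call(rbind, lapply(1:10, function(r)
    data.frame(element = "C", name = "CA", x = r * 4, y = 0, z = 0,
               resname = "ALA", resid = r, chain = "A", charge = 0L,
               class = "protein")))
  rec <- mol_system(atoms)
  attr(rec, "sse") <- list(helix = data.frame(chain = "A", start = 4, end = 8),
                           sheet = NULL)
  out <- defragment(paste0("A|", c(5, 6)), rec, max_gap = 0, min_fragment = 1)
  expect_setequal(out, paste0("A|", 4:8))
})

test_that("capping severs backbone bonds with correctly placed hydrogens", {
  pocket <- make_toy_pocket(seed = 1, n_residues = 20)
  # two internal fragments: residues 4-6 and 12-14
  sel <- paste0("A|", c(4:6, 12:14))
  red <- build_reduced(pocket, sel)
  caps <- red$system$atoms[red$system$atoms$class == "cap", , drop = FALSE]
  # each fragment is internal: one N-cap and one C-cap each
  expect_equal(nrow(caps), 4L)
  a <- pocket$atoms
  for (frag_start in c(4L, 12L)) {
    n_atom <- a[a$resid == frag_start & a$name == "N", ]
    c_prev <- a[a$resid == frag_start - 1L & a$name == "C", ]
    cap <- caps[caps$resid == frag_start, ]
    v_cap <- c(cap$x - n_atom$x, cap$y - n_atom$y, cap$z - n_atom$z)
    v_bond <- c(c_prev$x - n_atom$x, c_prev$y - n_atom$y, c_prev$z - n_atom$z)
    expect_equal(sqrt(sum(v_cap^2)), 1.01, tolerance = 1e-3)
    cosang <- sum(v_cap * v_bond) / sqrt(sum(v_cap^2) * sum(v_bond^2))
    expect_gt(cosang, cos(1 * pi / 180))  # collinear to 1 degree
  }
  c_caps <- caps[caps$resid %in% c(6L, 14L), ]
  for (k in seq_len(nrow(c_caps))) {
    frag_end <- c_caps$resid[k]
    c_atom <- a[a$resid == frag_end & a$name == "C", ]
    n_next <- a[a$resid == frag_end + 1L & a$name == "N", ]
    v_cap <- c(c_caps$x[k] - c_atom$x, c_caps$y[k] - c_atom$y,
               c_caps$z[k] - c_atom$z)
    v_bond <- c(n_next$x - c_atom$x, n_next$y - c_atom$y, n_next$z - c_atom$z)
    expect_equal(sqrt(sum(v_cap^2)), 1.09, tolerance = 1e-3)
    cosang <- sum(v_cap * v_bond) / sqrt(sum(v_cap^2) * sum(v_bond^2))
    expect_gt(cosang, cos(1 * pi / 180))
  }
})

test_that("a contiguous full-chain selection needs no caps", {
  pocket <- make_toy_pocket(seed = 1, n_residues = 10)
  sel <- residue_index(pocket, classes = "protein")$key
  red <- build_reduced(pocket, sel)
  expect_equal(sum(red$system$atoms$class == "cap"), 0L)
  expect_equal(sum(red$system$atoms$class == "protein"),
               sum(pocket$atoms$class == "protein"))
})

test_that("cluster atoms keep receptor coordinates and the rule-sum charge", {
  pocket <- make_toy_pocket(seed = 4)
  sel <- paste0("A|", c(2:8, 20:26))
  red <- build_reduced(pocket, sel)
  a <- red$system$atoms
  prov <- red$provenance
  non_cap <- !is.na(prov$source_atom)
  src <- pocket$atoms[prov$source_atom[non_cap], ]
  expect_equal(a[prov$cluster_atom[non_cap], c("x", "y", "z")],
               src[, c("x", "y", "z")], ignore_attr = TRUE)
  # charge equals the residue-rule sum over retained residues + ions
  keys <- paste(pocket$atoms$chain, pocket$atoms$resid, sep = "|")
  manual <- sum(pocket$atoms$charge[keys %in% sel |
                                    pocket$atoms$class %in% c("water", "ion")])
  expect_equal(red$charge, manual)
  # every severed boundary carries exactly one cap
  expect_equal(sum(a$class == "cap"), 4L)
})

test_that("a selected residue missing backbone atoms is reported by name", {
  atoms <- do.call(rbind, lapply(1:4, function(r)
    data.frame(element = "C", name = c("CA"), x = r * 4, y = 0, z = 0,
               resname = "ALA", resid = r, chain = "A", charge = 0L,
               class = "protein")))
  rec <- mol_system(atoms)
  expect_error(build_reduced(rec, c("A|2", "A|3")), "A\\|2")
})
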