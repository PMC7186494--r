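# Structure and pose-library I/O: PDB receptors (via bio3d), SDF/MOL2 pose
# records with formal charges, manifest sidecars, residue charge rules and
# water/ion environment selection.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SPC")
ION_RESNAMES   <- c("CA", "ZN", "MG", "NA", "K", "CL", "MN", "FE")
ION_CHARGE     <- c(Ca = 2L, Zn = 2L, Mg = 2L, Mn = 2L, Fe = 2L,
                    Na = 1L, K = 1L, Cl = -1L)

STANDARD_AA <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                 "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

# residue-level formal charge rules: carboxylates -1, guanidinium/ammonium +1.
# The named atom carries the charge; side-chain fallback when absent.
RESIDUE_CHARGE_RULE <- list(
  ASP = list(charge = -1L, atom = "OD2"),
  GLU = list(charge = -1L, atom = "OE2"),
  LYS = list(charge = +1L, atom = "NZ"),
  ARG = list(charge = +1L, atom = "NH2")
)

#' Read a receptor structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper classifies each
#' atom as protein, water or ion by residue name, fills in elements missing
#' from the element column using a fixed atom-name rule table (an atom named
#' `CA` is carbon inside an amino-acid residue but a calcium ion when it is a
#' residue of its own), honours CONECT records and infers peptide and
#' intra-residue bonds from interatomic distances against covalent radii.
#'
#' @param path path to a PDB coordinate file
#' @param infer_bonds perceive covalent bonds by distance (default TRUE)
#' @return a [mol_system()] with atoms in file order; HELIX/SHEET annotations,
#'   when present, are attached as the `sse` attribute (a list with data
#'   frames `helix` and `sheet` of chain/start/end ranges)
#' @export
read_receptor <- function(path, infer_bonds = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  n <- nrow(at)
  if (!n) stop("PDB file contains no atoms: ", path)
  resname <- toupper(trimws(at$resid))
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  cls <- classify_residue(resname, at$elety, at$resno, chain)
  element <- at$elesy
  missing_el <- is.na(element) | trimws(element) == ""
  if (any(missing_el)) {
    element[missing_el] <- infer_element(at$elety[missing_el],
                                         cls[missing_el], resname[missing_el])
  }
  element <- normalize_element(element)
  unknown <- !element %in% PERIODIC_SYMBOLS
  if (any(unknown)) {
    k <- which(unknown)[1L]
    stop("unknown element for atom ", at$eleno[k], " (name '", at$elety[k],
         "', residue ", resname[k], " ", at$resno[k], ")")
  }
  atoms <- data.frame(element = element, name = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      resname = resname, resid = at$resno, chain = chain,
                      charge = 0L, class = cls, stringsAsFactors = FALSE)
  bonds <- read_conect(path)
  if (infer_bonds) bonds <- rbind(bonds, perceive_bonds(atoms))
  sys <- mol_system(atoms, bonds)
  sse <- extract_sse(pdb)
  if (!is.null(sse)) attr(sys, "sse") <- sse
  sys
}

classify_residue <- function(resname, name, resno, chain) {
  cls <- rep("protein", length(resname))
  cls[resname %in% WATER_RESNAMES] <- "water"
  # an ion is a one-atom residue with an ion residue name
  key <- paste(chain, resno, resname)
  sizes <- table(key)
  cls[resname %in% ION_RESNAMES & sizes[key] == 1L] <- "ion"
  cls
}

# Fixed rule table for PDB files lacking the element column. Leading digits
# are stripped; calcium vs C-alpha is disambiguated by residue class.
infer_element <- function(name, cls, resname) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(name)))
  out <- character(length(nm))
  for (k in seq_along(nm)) {
    x <- nm[k]
    out[k] <-
      if (cls[k] == "ion") {
        two <- paste0(substr(x, 1, 1), tolower(substr(x, 2, 2)))
        if (two %in% PERIODIC_SYMBOLS) two else substr(x, 1, 1)
      } else if (grepl("^H", x)) "H"
      else if (x %in% c("CL") && !resname[k] %in% STANDARD_AA) "Cl"
      else if (grepl("^BR", x)) "Br"
      else substr(x, 1, 1)
  }
  out
}

read_conect <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[startsWith(ln, "CONECT")]
  if (!length(ln)) return(empty_bonds())
  pairs <- do.call(rbind, lapply(ln, function(l) {
    flds <- suppressWarnings(as.integer(
      substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2L) return(NULL)
    cbind(i = flds[1L], j = flds[-1L])
  }))
  if (is.null(pairs)) return(empty_bonds())
  data.frame(i = pairs[, 1], j = pairs[, 2], order = 1L)
}

# distance-based perception: bonded if r < r_cov(i) + r_cov(j) + 0.4 A;
# never bonds water/ion atoms to anything outside their own residue
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(empty_bonds())
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- COVALENT_RADIUS[atoms$element]
  rad[is.na(rad)] <- 0.8
  res <- residue_key(atoms)
  out_i <- integer(); out_j <- integer()
  cut <- max(rad) * 2 + 0.4
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d2 <- colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2)
    cand <- j[d2 < cut^2]
    if (!length(cand)) next
    d <- sqrt(d2[match(cand, j)])
    ok <- d < (rad[i] + rad[cand] + 0.4) & d > 0.4
    cand <- cand[ok]
    # waters and ions never bond across residues
    sep <- atoms$class[cand] %in% c("water", "ion") | atoms$class[i] %in% c("water", "ion")
    cand <- cand[!sep | res[cand] == res[i]]
    out_i <- c(out_i, rep.int(i, length(cand))); out_j <- c(out_j, cand)
  }
  if (!length(out_i)) return(empty_bonds())
  data.frame(i = out_i, j = out_j, order = 1L)
}

extract_sse <- function(pdb) {
  grab <- function(x) {
    if (is.null(x) || !length(x$start)) return(NULL)
    data.frame(chain = as.character(x$chain),
               start = as.integer(x$start), end = as.integer(x$end))
  }
  h <- grab(pdb$helix); s <- grab(pdb$sheet)
  if (is.null(h) && is.null(s)) return(NULL)
  list(helix = h, sheet = s)
}

#' Write a system as a PDB file
#'
#' Delegates formatting to [bio3d::write.pdb()]. Cap hydrogens introduced by
#' the cutout stage are flagged through the segment identifier `CAP` so a
#' reduced system remains distinguishable after a round trip.
#'
#' @param sys a [mol_system()]
#' @param path output path
#' @export
write_pdb_system <- function(sys, path) {
  a <- sys$atoms
  type <- ifelse(a$class %in% c("water", "ion", "ligand"), "HETATM", "ATOM")
  segid <- ifelse(a$class == "cap", "CAP", "")
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = a$resid, resid = a$resname, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   segid = segid, elesy = a$element)
  invisible(path)
}

#' Write a system in XYZ format (engine job geometry)
#' @param sys a [mol_system()]
#' @param path output path
#' @param comment second-line comment
#' @export
write_xyz <- function(sys, path, comment = "") {
  a <- sys$atoms
  lines <- c(sprintf("%d", nrow(a)), comment,
             sprintf("%-2s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z))
  writeLines(lines, path)
  invisible(path)
}

# --- pose libraries ---------------------------------------------------------

#' Read a library manifest
#'
#' The manifest is a required tab-separated sidecar with columns
#' `state_id`, `parent_id` and `label` (`ligand` or `decoy`): molecules can be
#' enumerated as several protonation or chirality states, and collapsing
#' states to one hit-list row needs an explicit parent mapping.
#'
#' @param path TSV file with a header row
#' @return data.frame with character columns state_id, parent_id and a logical
#'   `is_ligand`
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("state_id", "parent_id", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$state_id))
    stop("duplicate state_id in manifest: ",
         m$state_id[duplicated(m$state_id)][1L])
  bad <- !m$label %in% c("ligand", "decoy")
  if (any(bad)) stop("manifest label must be 'ligand' or 'decoy', got: ",
                     m$label[bad][1L])
  m$is_ligand <- m$label == "ligand"
  m
}

#' Write a library manifest
#' @param manifest data.frame with state_id, parent_id, label
#' @param path output TSV path
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("state_id", "parent_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read docked poses from an SDF or MOL2 file
#'
#' One record per molecule state, holding the single lowest-docking-energy
#' conformation for that state. Bonds and formal charges are taken from the
#' record (`M  CHG` blocks in SDF; partial charges in MOL2 are rounded to the
#' nearest integer only when a `FORMAL_CHARGES` comment requests it, else
#' charges default to 0 unless given in atom status bits). The record title
#' is the state id and must have a manifest row.
#'
#' @param path SDF (V2000) or MOL2 file; format chosen by extension
#' @param manifest data.frame from [read_manifest()]
#' @return list of `docked_pose` objects: each has `state_id`, `parent_id`,
#'   `is_ligand`, `system` (a [mol_system()] of class-`ligand` atoms) and
#'   optional `de` (docking energy, from an SDF data field named `DE`)
#' @export
read_poses <- function(path, manifest) {
  ext <- tolower(tools::file_ext(path))
  recs <- switch(ext,
                 sdf = , sd = , mol = parse_sdf(path),
                 mol2 = parse_mol2(path),
                 stop("unsupported pose format: .", ext))
  lapply(recs, function(r) {
    row <- match(r$state_id, manifest$state_id)
    if (is.na(row)) stop("pose record '", r$state_id, "' has no manifest row")
    if (!nrow(r$system$atoms)) stop("zero-atom pose record: ", r$state_id)
    docked_pose(r$state_id, manifest$parent_id[row], r$system,
                is_ligand = manifest$is_ligand[row], de = r$de)
  })
}

#' Construct a docked pose
#' @param state_id unique state identifier
#' @param parent_id parent molecule identifier
#' @param system ligand [mol_system()] in the docked conformation
#' @param is_ligand logical label from the manifest
#' @param de docking energy used to select this conformation (optional)
#' @export
docked_pose <- function(state_id, parent_id, system, is_ligand = NA, de = NA_real_) {
  system$atoms$class <- "ligand"
  structure(list(state_id = state_id, parent_id = parent_id,
                 system = system, is_ligand = is_ligand, de = de),
            class = "docked_pose")
}

#' @export
print.docked_pose <- function(x, ...) {
  cat(sprintf("<docked_pose> %s (parent %s, %s): %d atoms, charge %+d\n",
              x$state_id, x$parent_id,
              if (isTRUE(x$is_ligand)) "ligand" else "decoy",
              nrow(x$system$atoms), x$system$charge))
  invisible(x)
}

parse_sdf <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ends <- which(trimws(ln) == "$$$$")
  if (!length(ends)) ends <- length(ln)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- list()
  for (b in seq_along(starts)) {
    block <- ln[starts[b]:ends[b]]
    block <- block[cumsum(trimws(block) != "") > 0 | trimws(block) != ""]
    if (!length(block) || all(trimws(block) %in% c("", "$$$$"))) next
    title <- trimws(block[1L])
    counts <- block[4L]
    na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na)) stop("SDF counts line unreadable in record ", b, " of ", path)
    atom_lines <- block[5:(4 + na)]
    atoms <- data.frame(
      x = as.numeric(substr(atom_lines, 1, 10)),
      y = as.numeric(substr(atom_lines, 11, 20)),
      z = as.numeric(substr(atom_lines, 21, 30)),
      element = trimws(substr(atom_lines, 32, 34)),
      stringsAsFactors = FALSE)
    atoms$name <- paste0(atoms$element, seq_len(na))
    atoms$charge <- 0L
    bonds <- empty_bonds()
    if (nb > 0L) {
      bl <- block[(5 + na):(4 + na + nb)]
      bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                          j = as.integer(substr(bl, 4, 6)),
                          order = as.integer(substr(bl, 7, 9)))
    }
    # properties block: M  CHG overrides all charges
    prop <- block[grepl("^M  CHG", block)]
    for (p in prop) {
      flds <- as.numeric(strsplit(trimws(substr(p, 7, nchar(p))), "\\s+")[[1]])
      cnt <- flds[1L]
      for (k in seq_len(cnt)) {
        atoms$charge[flds[2 * k]] <- as.integer(flds[2 * k + 1])
      }
    }
    de <- NA_real_
    de_at <- grep("^> *<DE>", block)
    if (length(de_at)) de <- suppressWarnings(as.numeric(trimws(block[de_at[1L] + 1L])))
    recs[[length(recs) + 1L]] <-
      list(state_id = title, system = mol_system(atoms, bonds), de = de)
  }
  recs
}

parse_mol2 <- function(path) {
  ln <- readLines(path, warn = FALSE)
  mol_at <- grep("^@<TRIPOS>MOLECULE", ln)
  if (!length(mol_at)) stop("not a MOL2 file (no @<TRIPOS>MOLECULE): ", path)
  bounds <- c(mol_at, length(ln) + 1L)
  recs <- list()
  for (b in seq_along(mol_at)) {
    block <- ln[bounds[b]:(bounds[b + 1L] - 1L)]
    title <- trimws(block[2L])
    counts <- as.integer(strsplit(trimws(block[3L]), "\\s+")[[1]])
    na <- counts[1L]; nb <- if (length(counts) > 1L) counts[2L] else 0L
    at0 <- grep("^@<TRIPOS>ATOM", block)[1L]
    if (is.na(at0)) stop("MOL2 record '", title, "' lacks an ATOM section")
    parse_row <- function(l) strsplit(trimws(l), "\\s+")[[1]]
    arows <- lapply(block[(at0 + 1L):(at0 + na)], parse_row)
    element <- vapply(arows, function(r) sub("\\..*$", "", r[6L]), "")
    atoms <- data.frame(
      name = vapply(arows, `[`, "", 2L),
      x = as.numeric(vapply(arows, `[`, "", 3L)),
      y = as.numeric(vapply(arows, `[`, "", 4L)),
      z = as.numeric(vapply(arows, `[`, "", 5L)),
      element = element, stringsAsFactors = FALSE)
    atoms$charge <- vapply(arows, function(r)
      if (length(r) >= 9L) as.numeric(r[9L]) else 0, 0)
    # MOL2 charge column is partial charge; treat as formal only when integral
    atoms$charge <- ifelse(abs(atoms$charge - round(atoms$charge)) < 1e-6,
                           as.integer(round(atoms$charge)), 0L)
    bonds <- empty_bonds()
    if (nb > 0L) {
      bd0 <- grep("^@<TRIPOS>BOND", block)[1L]
      brows <- lapply(block[(bd0 + 1L):(bd0 + nb)], parse_row)
      ord <- vapply(brows, `[`, "", 4L)
      bonds <- data.frame(i = as.integer(vapply(brows, `[`, "", 2L)),
                          j = as.integer(vapply(brows, `[`, "", 3L)),
                          order = ifelse(ord %in% c("ar", "am"), 1L,
                                         suppressWarnings(as.integer(ord))))
      bonds$order[is.na(bonds$order)] <- 1L
    }
    recs[[length(recs) + 1L]] <-
      list(state_id = title, system = mol_system(atoms, bonds), de = NA_real_)
  }
  recs
}

#' Write pose systems as an SDF (V2000) file
#'
#' Formal charges are emitted as `M  CHG` lines; a numeric `de` is written as
#' a `<DE>` data field.
#'
#' @param poses list of `docked_pose` (or a single one)
#' @param path output path
#' @export
write_sdf <- function(poses, path) {
  if (inherits(poses, "docked_pose")) poses <- list(poses)
  con <- file(path, "w"); on.exit(close(con))
  for (p in poses) {
    a <- p$system$atoms; b <- p$system$bonds
    writeLines(c(p$state_id, "  qmscreen", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(a), nrow(b))), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b))
      writeLines(sprintf("%3d%3d%3d  0", b$i, b$j, b$order), con)
    chg <- which(a$charge != 0L)
    if (length(chg)) {
      for (start in seq(1L, length(chg), by = 8L)) {
        idx <- chg[start:min(length(chg), start + 7L)]
        writeLines(paste0("M  CHG", sprintf("%3d", length(idx)),
                          paste0(sprintf("%4d%4d", idx, a$charge[idx]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    if (!is.na(p$de)) writeLines(c("> <DE>", format(p$de), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

# --- charge rules and environment selection ---------------------------------

#' Assign formal charges by residue rule
#'
#' Protein residues get their physiological-pH formal charges: Asp and Glu
#' \eqn{-1} (carboxylate), Arg and Lys \eqn{+1}; His stays neutral with the
#' tautomer implied by the input hydrogens. Monatomic ions are charged by
#' element (Ca/Zn/Mg/Mn/Fe +2, Na/K +1, Cl \eqn{-1}). Waters, ligand atoms and
#' cap hydrogens are left untouched. The operation recomputes protein/ion
#' charges from scratch, so it is idempotent.
#'
#' @param sys a [mol_system()]
#' @param charge_termini charge free chain termini (N-terminus +1 on N,
#'   C-terminus -1 on OXT/terminal O)? Default FALSE: intact chains are
#'   modeled neutral.
#' @return the system with updated atomic charges and total charge
#' @export
assign_formal_charges <- function(sys, charge_termini = FALSE) {
  a <- sys$atoms
  prot <- a$class == "protein"
  a$charge[prot] <- 0L
  res <- residue_key(a)
  for (key in unique(res[prot])) {
    rows <- which(res == key & prot)
    rn <- a$resname[rows[1L]]
    rule <- RESIDUE_CHARGE_RULE[[rn]]
    if (!is.null(rule)) {
      target <- rows[match(rule$atom, a$name[rows])]
      if (is.na(target)) {
        # fallback: last side-chain atom, else last atom of the residue
        sc <- rows[!a$name[rows] %in% c("N", "CA", "C", "O", "OXT")]
        target <- if (length(sc)) sc[length(sc)] else rows[length(rows)]
      }
      a$charge[target] <- rule$charge
    } else if (!rn %in% STANDARD_AA) {
      warning("no charge rule for residue ", rn, " (", key, "); assigned 0")
    }
  }
  ion <- a$class == "ion"
  if (any(ion)) {
    q <- ION_CHARGE[a$element[ion]]
    q[is.na(q)] <- 0L
    a$charge[ion] <- q
  }
  if (charge_termini) {
    for (ch in unique(a$chain[prot])) {
      rows <- which(prot & a$chain == ch)
      first_res <- res[rows[1L]]; last_res <- res[rows[length(rows)]]
      nterm <- rows[res[rows] == first_res & a$name[rows] == "N"]
      if (length(nterm)) a$charge[nterm[1L]] <- a$charge[nterm[1L]] + 1L
      cand <- rows[res[rows] == last_res & a$name[rows] %in% c("OXT", "O")]
      if (length(cand)) a$charge[cand[1L]] <- a$charge[cand[1L]] - 1L
    }
  }
  sys$atoms <- a
  sys$charge <- sum(a$charge)
  sys
}

#' Retain binding-site waters and ions
#'
#' Keeps only those water molecules whose nearest heavy atom lies within
#' `water_cutoff` of a reference ligand's heavy atoms, and ions within
#' `ion_cutoff`; all protein atoms pass through unchanged. These are the
#' environment-retention radii applied when preparing a receptor (waters
#' within 4 A of the native ligand, co-factor ions within 8 A).
#'
#' @param receptor a [mol_system()]
#' @param reference_ligand a [mol_system()] giving the reference pose, or NULL
#' @param water_cutoff,ion_cutoff retention radii in Angstrom (defaults 4, 8)
#' @return the receptor with non-retained waters/ions removed
#' @export
select_environment <- function(receptor, reference_ligand,
                               water_cutoff = 4.0, ion_cutoff = 8.0) {
  stopifnot(water_cutoff > 0, ion_cutoff > 0)
  a <- receptor$atoms
  if (is.null(reference_ligand) || !nrow(reference_ligand$atoms)) {
    if (any(a$class %in% c("water", "ion")))
      warning("no reference ligand: dropping all waters and ions")
    return(sys_subset(receptor, !a$class %in% c("water", "ion")))
  }
  ref <- reference_ligand$atoms
  ref_xyz <- as.matrix(ref[ref$heavy, c("x", "y", "z"), drop = FALSE])
  keep <- a$class == "protein"
  for (spec in list(list(cls = "water", cut = water_cutoff),
                    list(cls = "ion", cut = ion_cutoff))) {
    d <- residue_min_dist(receptor, ref_xyz, classes = spec$cls)
    kept_keys <- names(d)[d <= spec$cut]
    keep <- keep | (a$class == spec$cls & residue_key(a) %in% kept_keys)
  }
  sys_subset(receptor, keep)
}
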