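#' Construct a molecular system
#'
#' A `molsys` is the package's universal container for a receptor, a ligand,
#' a binding-site cluster or a protein--ligand complex: a flat atom table plus
#' an explicit bond list and a total formal charge.
#'
#' @param atoms data.frame with one row per atom and columns `element`
#'   (periodic-table symbol), `name` (atom name), `x`, `y`, `z` (Cartesian,
#'   Angstrom), `resname`, `resid` (integer), `chain`, `charge` (integer
#'   formal charge, e) and `class` (one of `"protein"`, `"water"`, `"ion"`,
#'   `"ligand"`, `"cap"`). Missing optional columns are filled with defaults.
#' @param bonds data.frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order`. May be empty.
#'
#' @return An object of class `molsys`: a list with elements `atoms`, `bonds`
#'   and `charge` (the sum of atomic formal charges). A logical `heavy`
#'   column (element != "H") is derived and kept in sync with `element`.
#' @export
mol_system <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  defaults <- list(name = NA_character_, resname = "LIG", resid = 1L,
                   chain = "A", charge = 0L, class = "ligand")
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  }
  req <- c("element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  atoms$element <- normalize_element(atoms$element)
  bad <- !atoms$element %in% PERIODIC_SYMBOLS
  if (any(bad)) {
    stop("unknown element symbol(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "),
         " (atom rows ", paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atomic coordinates")
  atoms$resid <- as.integer(atoms$resid)
  atoms$charge <- as.integer(round(atoms$charge))
  atoms$heavy <- atoms$element != "H"
  rownames(atoms) <- NULL

  if (is.null(bonds)) bonds <- empty_bonds()
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (!all(c("i", "j") %in% names(bonds))) stop("bonds need columns i, j")
    if (is.null(bonds$order)) bonds$order <- 1L
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    n <- nrow(atoms)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references atom index outside 1..", n)
    if (any(bonds$i == bonds$j)) stop("bond joins an atom to itself")
    # canonical i < j ordering, duplicates collapsed
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
    rownames(bonds) <- NULL
  } else {
    bonds <- empty_bonds()
  }

  structure(list(atoms = atoms, bonds = bonds,
                 charge = sum(atoms$charge)),
            class = "molsys")
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = integer())
}

#' @export
print.molsys <- function(x, ...) {
  cls <- table(x$atoms$class)
  cat(sprintf("<molsys> %d atoms (%d heavy), %d bonds, charge %+d\n",
              nrow(x$atoms), sum(x$atoms$heavy), nrow(x$bonds), x$charge))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  invisible(x)
}

#' Atomic coordinates as an n x 3 matrix
#' @param sys a `molsys`
#' @return numeric matrix with columns x, y, z
#' @export
sys_coords <- function(sys) {
  as.matrix(sys$atoms[, c("x", "y", "z")])
}

#' Replace atomic coordinates
#' @param sys a `molsys`
#' @param xyz n x 3 numeric matrix
#' @return the updated `molsys`
#' @export
sys_set_coords <- function(sys, xyz) {
  stopifnot(nrow(xyz) == nrow(sys$atoms), ncol(xyz) == 3)
  sys$atoms$x <- xyz[, 1]; sys$atoms$y <- xyz[, 2]; sys$atoms$z <- xyz[, 3]
  sys
}

#' Number of atoms in a system
#' @param sys a `molsys`
#' @export
n_atoms <- function(sys) nrow(sys$atoms)

#' Extract a subset of atoms as a new system
#'
#' Bonds internal to the kept set are retained and re-indexed.
#'
#' @param sys a `molsys`
#' @param keep logical or integer index over atoms
#' @export
sys_subset <- function(sys, keep) {
  idx <- seq_len(nrow(sys$atoms))[keep]
  map <- integer(nrow(sys$atoms)); map[idx] <- seq_along(idx)
  b <- sys$bonds
  b <- b[b$i %in% idx & b$j %in% idx, , drop = FALSE]
  if (nrow(b)) { b$i <- map[b$i]; b$j <- map[b$j] }
  mol_system(sys$atoms[idx, , drop = FALSE], b)
}

#' Concatenate two systems (e.g. pocket cluster + ligand pose)
#' @param a,b `molsys` objects
#' @return a `molsys` holding the atoms and bonds of both
#' @export
sys_combine <- function(a, b) {
  off <- nrow(a$atoms)
  bonds_b <- b$bonds
  if (nrow(bonds_b)) { bonds_b$i <- bonds_b$i + off; bonds_b$j <- bonds_b$j + off }
  cols <- union(names(a$atoms), names(b$atoms))
  for (col in setdiff(cols, names(a$atoms))) a$atoms[[col]] <- NA
  for (col in setdiff(cols, names(b$atoms))) b$atoms[[col]] <- NA
  mol_system(rbind(a$atoms[cols], b$atoms[cols]), rbind(a$bonds, bonds_b))
}

#' Residue index of a system
#'
#' Ordered table of distinct (chain, resid, resname, class) tuples in atom
#' order, with a stable key `"chain|resid"` used throughout the cutout and
#' relaxation modules.
#'
#' @param sys a `molsys`
#' @param classes restrict to these atom classes (default: all)
#' @return data.frame with columns `key`, `chain`, `resid`, `resname`, `class`
#' @export
residue_index <- function(sys, classes = NULL) {
  a <- sys$atoms
  if (!is.null(classes)) a <- a[a$class %in% classes, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(key = character(), chain = character(), resid = integer(),
                      resname = character(), class = character()))
  }
  key <- paste(a$chain, a$resid, sep = "|")
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first], resid = a$resid[first],
             resname = a$resname[first], class = a$class[first],
             stringsAsFactors = FALSE)
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resid, sep = "|")

#' Minimum heavy-atom distance from each residue to a reference point set
#'
#' @param sys a `molsys`
#' @param ref_xyz m x 3 matrix of reference (heavy-atom) coordinates
#' @param classes atom classes of `sys` to consider
#' @return named numeric vector: residue key -> minimum Euclidean distance
#'   between any heavy atom of the residue and any reference point
#' @export
residue_min_dist <- function(sys, ref_xyz, classes = "protein") {
  a <- sys$atoms
  sel <- a$class %in% classes & a$heavy
  a <- a[sel, , drop = FALSE]
  if (!nrow(a) || !nrow(ref_xyz)) return(stats::setNames(numeric(), character()))
  d <- min_dist_to_set(as.matrix(a[, c("x", "y", "z")]), ref_xyz)
  tapply(d, residue_key(a), min)
}

# rowwise minimum distance from pts (n x 3) to set (m x 3), vectorized
min_dist_to_set <- function(pts, set) {
  stopifnot(ncol(pts) == 3, ncol(set) == 3)
  s2 <- rowSums(set^2)
  out <- numeric(nrow(pts))
  # chunk to bound the n x m cross-product matrix
  chunk <- max(1L, floor(2e6 / max(1L, nrow(set))))
  for (start in seq(1L, nrow(pts), by = chunk)) {
    idx <- start:min(nrow(pts), start + chunk - 1L)
    p <- pts[idx, , drop = FALSE]
    cross <- p %*% t(set)
    d2 <- outer(rowSums(p^2), s2, "+") - 2 * cross
    out[idx] <- sqrt(pmax(0, apply(d2, 1L, min)))
  }
  out
}

# --- element bookkeeping ----------------------------------------------------

PERIODIC_SYMBOLS <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn")

normalize_element <- function(el) {
  el <- trimws(as.character(el))
  n2 <- nchar(el) >= 2
  out <- el
  out[!n2] <- toupper(el[!n2])
  out[n2] <- paste0(toupper(substr(el[n2], 1, 1)),
                    tolower(substr(el[n2], 2, nchar(el[n2]))))
  out
}

# single-bond covalent radii (Angstrom) for distance-based bond perception
COVALENT_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                     Na = 1.66, K = 2.03, Mg = 1.41, Ca = 1.76, Zn = 1.22)
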