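# Desk-scale synthetic fixtures: toy binding pockets with a charged rim,
# ligand/decoy pose libraries with designed energetic separation, and
# binormal ranked lists for metric oracles. All generators are deterministic
# per seed and emit standard formats (PDB/SDF + manifest TSV), so fixtures
# flow through the same entry points as real data.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a toy binding pocket
#'
#' A mini-protein whose residues line a concave hemispherical shell around
#' the origin (the binding site). Residues use a reduced atom alphabet --
#' backbone N, CA, C plus one pseudo-side-chain atom CB pointing into the
#' pocket -- which is enough to exercise cutout capping, residue charge
#' rules, environment retention and restrained relaxation without full
#' force-field typing. Half the residues are charged (two Asp for each
#' Lys) giving the pocket floor a net negative charge under a near-neutral
#' shell; two waters (one inside the 4 A retention radius of a ligand at the
#' pocket site, one far outside) and one Ca2+ ion in the open mouth region
#' (within its 8 A retention radius) are included.
#'
#' @param seed RNG seed for the small coordinate jitter
#' @param n_residues number of shell residues (default 30)
#' @param pocket_radius shell radius in Angstrom (default 10)
#' @return a [mol_system()] with formal charges assigned
#' @export
make_toy_pocket <- function(seed = 0, n_residues = 30L, pocket_radius = 10.0) {
  stopifnot(n_residues >= 3L, pocket_radius > 3)
  with_seed(seed, {
    i <- seq_len(n_residues)
    # spiral over a lower-hemisphere band; pocket mouth opens toward +z
    # equal-area latitude steps keep the spiral density uniform on the shell
    polar <- acos(seq(cos(0.55 * pi), cos(0.95 * pi),
                      length.out = n_residues))
    azim <- 2.39996 * i  # golden angle
    ca <- pocket_radius * cbind(sin(polar) * cos(azim),
                                sin(polar) * sin(azim),
                                cos(polar))
    ca <- ca + matrix(stats::runif(3 * n_residues, -0.05, 0.05),
                      ncol = 3L)
    nxt <- rbind(ca[-1L, , drop = FALSE], 2 * ca[n_residues, ] - ca[n_residues - 1L, ])
    chain_dir <- nxt - ca
    chain_dir <- chain_dir / sqrt(rowSums(chain_dir^2))
    outward <- ca / sqrt(rowSums(ca^2))
    inward <- -outward
    # unit tangent in the shell surface, roughly along the chain chord
    t2 <- chain_dir - outward * rowSums(chain_dir * outward)
    t2 <- t2 / sqrt(rowSums(t2^2))
    # charge layout: Lys at the mouth (shallow), Asp lining the bottom where
    # the ligand site is, neutral residues between -- a negatively charged
    # floor with a near-neutral overall shell
    n_lys <- max(1L, round(n_residues / 6))
    n_asp <- max(1L, round(n_residues / 3))
    resnames <- c(rep("LYS", n_lys),
                  rep(c("ALA", "SER", "LEU"),
                      length.out = n_residues - n_lys - n_asp),
                  rep("ASP", n_asp))
    rows <- vector("list", n_residues)
    for (k in i) {
      # bond lengths match the toy reference values exactly (N-CA 1.47,
      # CA-C/CA-CB 1.54) so the pocket is built strain-free; backbone N/C
      # lean outward to keep each residue's tangential footprint small --
      # spatially neighbouring shell residues must not enter LJ contact
      pos <- rbind(N = ca[k, ] + 1.47 * (0.924 * outward[k, ] + 0.383 * t2[k, ]),
                   CA = ca[k, ],
                   C = ca[k, ] + 1.54 * (0.924 * outward[k, ] - 0.383 * t2[k, ]),
                   CB = ca[k, ] + 1.54 * inward[k, ])
      rows[[k]] <- data.frame(
        element = c("N", "C", "C", "C"),
        name = c("N", "CA", "C", "CB"),
        x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
        resname = resnames[k], resid = k, chain = "A",
        charge = 0L, class = "protein", stringsAsFactors = FALSE)
    }
    solvent <- data.frame(
      element = c("O", "O", "Ca"),
      name = c("O", "O", "CA"),
      x = c(3.4, 2.0, 0.0), y = c(1.4, 1.5, 5.2),
      z = c(-0.5, 12.0, 1.5),
      resname = c("HOH", "HOH", "CA"),
      resid = c(900L, 901L, 950L), chain = "W",
      charge = 0L, class = c("water", "water", "ion"),
      stringsAsFactors = FALSE)
    atoms <- rbind(do.call(rbind, rows), solvent)
    # intra-residue backbone bonds and the CA-CB stub; no inter-residue
    # bonds (the shell spacing is wider than a peptide bond)
    nb <- nrow(atoms)
    res_start <- seq(1L, by = 4L, length.out = n_residues)
    bonds <- data.frame(
      i = c(res_start, res_start + 1L, res_start + 1L),
      j = c(res_start + 1L, res_start + 2L, res_start + 3L),
      order = 1L)
    assign_formal_charges(mol_system(atoms, bonds))
  })
}

# a rigid diatomic probe: carbon plus a charged head group (N+ or O-);
# with a single bond it stays rigid under the toy potential, which carries
# no angle terms
probe_molecule <- function(center, charge = 0L, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  head_el <- if (charge > 0L) "N" else if (charge < 0L) "O" else "C"
  r0 <- toy_r0("C", head_el)
  xyz <- rbind(center, center + r0 * axis)
  atoms <- data.frame(element = c("C", head_el),
                      name = c("C1", paste0(head_el, "2")),
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      resname = "LIG", resid = 1L, chain = "L",
                      charge = c(0L, charge),
                      class = "ligand", stringsAsFactors = FALSE)
  mol_system(atoms, data.frame(i = 1L, j = 2L, order = 1L))
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate a synthetic ligand/decoy pose library
#'
#' Emulates a benchmark library of actives plus property-matched decoys:
#' every molecule is a rigid diatomic probe with net charge +1 (matched atom
#' count and net charge across classes). Ligands sit in the pocket mouth
#' where the net-negative charged rim rewards them electrostatically; decoys
#' share the composition but are displaced out of the pocket along its axis,
#' losing the favourable contacts, so the toy interaction energy separates
#' the classes by a designed margin. The first two ligand parents and the
#' first decoy parent are emitted as two protonation-like states (charged
#' and neutral) to exercise state collapsing, and the final decoy pose
#' carries a deliberate atom clash to exercise failure handling.
#'
#' @param seed RNG seed
#' @param n_ligands,n_decoys class sizes (defaults 20 and 180)
#' @param displacement how far decoys sit above the pocket mouth, A
#'   (default 11; larger = wider energetic margin)
#' @return list with `poses` (list of `docked_pose`) and `manifest`
#'   (data.frame state_id, parent_id, label)
#' @export
make_library <- function(seed = 0, n_ligands = 20L, n_decoys = 180L,
                         displacement = 11.0) {
  stopifnot(n_ligands >= 1L, n_decoys >= 1L)
  with_seed(seed, {
    poses <- list(); manifest <- list()
    emit <- function(parent, state, label, center, charge, clash = FALSE) {
      sys <- probe_molecule(center, charge = charge, axis = random_unit())
      if (clash) {
        # put one atom essentially on top of the other: backend must fail
        sys$atoms$x[2L] <- sys$atoms$x[1L] + 0.05
        sys$atoms$y[2L] <- sys$atoms$y[1L]
        sys$atoms$z[2L] <- sys$atoms$z[1L]
      }
      poses[[length(poses) + 1L]] <<- docked_pose(state, parent, sys,
                                                  is_ligand = label == "ligand")
      manifest[[length(manifest) + 1L]] <<-
        data.frame(state_id = state, parent_id = parent, label = label)
    }
    jitter3 <- function(s) stats::runif(3L, -s, s)
    for (k in seq_len(n_ligands)) {
      parent <- sprintf("LIG%03d", k)
      center <- c(0, 0, -3) + jitter3(0.35)
      emit(parent, paste0(parent, "_s1"), "ligand", center, charge = 1L)
      if (k <= 2L)  # second protonation-like state: neutral, shifted
        emit(parent, paste0(parent, "_s2"), "ligand",
             center + jitter3(0.3), charge = 0L)
    }
    for (k in seq_len(n_decoys)) {
      parent <- sprintf("DEC%03d", k)
      center <- c(0, 0, -3 + displacement) + jitter3(0.8)
      clash <- k == n_decoys
      emit(parent, paste0(parent, "_s1"), "decoy", center, charge = 1L,
           clash = clash)
      if (k == 1L)
        emit(parent, paste0(parent, "_s2"), "decoy",
             center + jitter3(0.3), charge = 0L)
    }
    list(poses = poses, manifest = do.call(rbind, manifest))
  })
}

#' Generate a ranked score/label list with a target AUC
#'
#' Binormal model: decoy scores are N(0, 1), ligand scores are
#' N(-delta, 1) with delta = sqrt(2) * qnorm(auc_target), which makes the
#' expected AUC (lower score = better) equal to `auc_target`. An
#' `auc_target` of 1 separates the classes deterministically.
#'
#' @param seed RNG seed
#' @param n total molecules
#' @param auc_target expected AUC in [0.5, 1]
#' @param frac_ligand ligand fraction (default 0.1)
#' @return data.frame with `parent_id`, `score`, `is_ligand`, plus `status`
#'   and `variant` columns so it feeds [build_hitlist()] directly
#' @export
make_ranked_list <- function(seed = 0, n = 500L, auc_target = 0.8,
                             frac_ligand = 0.1) {
  stopifnot(n >= 2L, auc_target >= 0, auc_target <= 1)
  with_seed(seed, {
    n_lig <- max(1L, round(n * frac_ligand))
    is_ligand <- c(rep(TRUE, n_lig), rep(FALSE, n - n_lig))
    dec <- stats::rnorm(n - n_lig)
    lig <- if (auc_target >= 1) {
      min(dec) - 1 - stats::runif(n_lig)
    } else {
      delta <- sqrt(2) * stats::qnorm(auc_target)
      stats::rnorm(n_lig, mean = -delta)
    }
    data.frame(parent_id = sprintf("M%04d", seq_len(n)),
               score = c(lig, dec), is_ligand = is_ligand,
               status = "converged", variant = "SYN",
               stringsAsFactors = FALSE)
  })
}
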