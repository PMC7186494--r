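# Single-point energy backends behind one contract: a deterministic classical
# toy potential (default; makes the whole pipeline testable at desk scale)
# and a file-dialect adapter for an external semi-empirical engine running
# PM7 with COSMO continuum solvation.

EV_TO_KCAL <- 23.060548867

#' Backend configuration
#'
#' @param backend `"toy"` (built-in deterministic potential, default) or
#'   `"engine"` (external semi-empirical program via job files)
#' @param eps solvent relative permittivity for the continuum model
#'   (default 78.4, water)
#' @param keywords extra engine keywords appended to the job header
#' @param timeout wall-clock limit in seconds for one engine job
#' @param scratch directory for engine job files
#' @param engine_cmd path to the engine executable; when empty, engine jobs
#'   are written but marked failed (to be farmed out and parsed later)
#' @param toy named list overriding toy-potential parameters: `kb`
#'   (bond force constant, kcal/mol/A^2), `v3` (torsion barrier, kcal/mol),
#'   `epsilon` (LJ well depth, kcal/mol), `sigma` (LJ minimum distance, A),
#'   `tau` (solvation coefficient, kcal/mol/e^2), `coulomb` (332.06
#'   kcal*A/mol/e^2)
#' @return a `backend_config` list
#' @export
backend_config <- function(backend = c("toy", "engine"), eps = 78.4,
                           keywords = character(), timeout = 600,
                           scratch = tempdir(), engine_cmd = "",
                           toy = list()) {
  backend <- match.arg(backend)
  stopifnot(eps >= 1)
  defaults <- list(kb = 300, v3 = 2, epsilon = 0.1, sigma = 3.4,
                   tau = 1.0, coulomb = 332.06)
  defaults[names(toy)] <- toy
  structure(list(backend = backend, eps = eps, keywords = keywords,
                 timeout = timeout, scratch = scratch,
                 engine_cmd = engine_cmd, toy = defaults),
            class = "backend_config")
}

energy_result <- function(total = NA_real_, gas = NA_real_,
                          solvation = NA_real_, sasa = NA_real_,
                          status = "converged", seconds = NA_real_,
                          reason = NULL) {
  structure(list(total = total, gas = gas, solvation = solvation,
                 sasa = sasa, status = status, seconds = seconds,
                 reason = reason),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  if (x$status == "converged")
    cat(sprintf("<energy_result> total %.4f kcal/mol (gas %.4f + solv %.4f)\n",
                x$total, x$gas, x$solvation))
  else
    cat("<energy_result> FAILED:", x$reason %||% "unknown", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-point energy of a system
#'
#' Dispatches to the configured backend. Deterministic for fixed input and
#' configuration; a geometry with overlapping atoms (any pair closer than
#' 0.3 A) yields a `failed` result rather than an error, mirroring how
#' non-converging engine jobs are excluded from a screen instead of aborting
#' it.
#'
#' @param system a [mol_system()] with coordinates and formal charges set
#' @param config a [backend_config()]
#' @return an `energy_result` with `total = gas + solvation` (kcal/mol) when
#'   converged
#' @export
single_point <- function(system, config = backend_config()) {
  switch(config$backend,
         toy = toy_energy(system, config = config),
         engine = engine_single_point(system, config))
}

# --- toy potential ----------------------------------------------------------

# reference bond lengths (A) per unordered element pair; 1.50 elsewhere
TOY_R0 <- c("C|C" = 1.54, "C|N" = 1.47, "C|O" = 1.43, "C|S" = 1.82,
            "N|O" = 1.40, "N|N" = 1.45, "O|O" = 1.48, "S|S" = 2.05,
            "C|H" = 1.09, "N|H" = 1.01, "O|H" = 0.96, "S|H" = 1.34)

toy_r0 <- function(e1, e2) {
  key <- ifelse(e1 < e2, paste(e1, e2, sep = "|"), paste(e2, e1, sep = "|"))
  r0 <- TOY_R0[key]
  r0[is.na(r0)] <- 1.50
  unname(r0)
}

#' Precompute the toy-potential topology of a system
#'
#' Bond terms with reference lengths, proper torsion quadruples around every
#' bond, and the nonbonded pair list (all atom pairs except those bonded or
#' sharing a bonded neighbour, i.e. 1-2 and 1-3 exclusions).
#'
#' @param system a [mol_system()]
#' @return a `toy_topology` list consumed by [toy_eval()]
#' @export
toy_topology <- function(system) {
  a <- system$atoms
  n <- nrow(a)
  b <- system$bonds
  nbrs <- vector("list", n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      nbrs[[b$i[k]]] <- c(nbrs[[b$i[k]]], b$j[k])
      nbrs[[b$j[k]]] <- c(nbrs[[b$j[k]]], b$i[k])
    }
  }
  # torsion quadruples a-b-c-d around each bond b-c
  tor <- list()
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      bi <- b$i[k]; ci <- b$j[k]
      for (ai in setdiff(nbrs[[bi]], ci)) {
        for (di in setdiff(nbrs[[ci]], bi)) {
          if (ai != di) tor[[length(tor) + 1L]] <- c(ai, bi, ci, di)
        }
      }
    }
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else
    matrix(integer(), ncol = 4L)
  # nonbonded pairs: exclude 1-2 and 1-3
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) mark(b$i[k], b$j[k])
    for (ctr in seq_len(n)) {
      nb <- nbrs[[ctr]]
      if (length(nb) > 1L) {
        cmb <- utils::combn(nb, 2L)
        for (k in seq_len(ncol(cmb))) mark(cmb[1L, k], cmb[2L, k])
      }
    }
  }
  if (n > 1L) {
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- !vapply(seq_len(nrow(ut)),
                    function(k) exists(paste(ut[k, 1L], ut[k, 2L]), envir = excl),
                    TRUE)
    pairs <- ut[keep, , drop = FALSE]
  } else pairs <- matrix(integer(), ncol = 2L)
  structure(list(n = n,
                 bond_i = b$i, bond_j = b$j,
                 bond_r0 = if (nrow(b)) toy_r0(a$element[b$i], a$element[b$j])
                           else numeric(),
                 torsions = torsions,
                 pair_i = pairs[, 1L], pair_j = pairs[, 2L],
                 q = as.numeric(a$charge)),
            class = "toy_topology")
}

#' Evaluate the toy potential on raw coordinates
#'
#' \deqn{G = \sum_{bonds} k_b (r - r_0)^2
#'        + \sum_{torsions} \tfrac{V_3}{2} (1 + \cos 3\varphi)
#'        + \sum_{pairs} \left[\epsilon\big((\sigma/r)^{12} - 2 (\sigma/r)^6\big)
#'        + 332.06\, q_i q_j / (4 r^2)\right] - \tau \sum_i q_i^2}
#'
#' The last sum is a Born-like self-solvation term, independent of geometry;
#' the Coulomb term uses a distance-dependent dielectric 4r. The analytic
#' gradient covers every geometry-dependent term.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param topo a [toy_topology()]
#' @param params toy parameter list (from [backend_config()]`$toy`)
#' @param gradient also return the n x 3 analytic gradient?
#' @return list with `total`, `gas`, `solvation`, and `grad` when requested
#' @export
toy_eval <- function(xyz, topo, params = backend_config()$toy,
                     gradient = FALSE) {
  n <- topo$n
  grad <- if (gradient) matrix(0, n, 3L) else NULL
  e_bond <- 0
  if (length(topo$bond_i)) {
    dvec <- xyz[topo$bond_i, , drop = FALSE] - xyz[topo$bond_j, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    dr <- r - topo$bond_r0
    e_bond <- params$kb * sum(dr^2)
    if (gradient) {
      coef <- 2 * params$kb * dr / r
      g <- dvec * coef
      grad <- grad + rowsum_into(g, topo$bond_i, n) -
        rowsum_into(g, topo$bond_j, n)
    }
  }
  e_tor <- 0
  if (nrow(topo$torsions)) {
    tt <- torsion_terms(xyz, topo$torsions, gradient)
    e_tor <- sum(params$v3 / 2 * (1 + cos(3 * tt$phi)))
    if (gradient) {
      dEdphi <- -(3 * params$v3 / 2) * sin(3 * tt$phi)
      for (col in 1:4) {
        grad <- grad + rowsum_into(tt$dphi[[col]] * dEdphi,
                                   topo$torsions[, col], n)
      }
    }
  }
  e_nb <- 0
  if (length(topo$pair_i)) {
    dvec <- xyz[topo$pair_i, , drop = FALSE] - xyz[topo$pair_j, , drop = FALSE]
    r2 <- rowSums(dvec^2)
    r <- sqrt(r2)
    sr6 <- (params$sigma^2 / r2)^3
    qq <- topo$q[topo$pair_i] * topo$q[topo$pair_j]
    e_lj <- params$epsilon * (sr6^2 - 2 * sr6)
    e_cl <- params$coulomb * qq / (4 * r2)
    e_nb <- sum(e_lj) + sum(e_cl)
    if (gradient) {
      # dE/dr / r, applied to the displacement vector
      dlj <- -12 * params$epsilon * (sr6^2 - sr6) / r2
      dcl <- -2 * params$coulomb * qq / (4 * r2^2)
      g <- dvec * (dlj + dcl)
      grad <- grad + rowsum_into(g, topo$pair_i, n) -
        rowsum_into(g, topo$pair_j, n)
    }
  }
  solvation <- -params$tau * sum(topo$q^2)
  gas <- e_bond + e_tor + e_nb
  out <- list(total = gas + solvation, gas = gas, solvation = solvation)
  if (gradient) out$grad <- grad
  out
}

# scatter-add rows of g (m x 3) into an n x 3 matrix by index
rowsum_into <- function(g, idx, n) {
  out <- matrix(0, n, 3L)
  s <- rowsum(g, idx)
  out[as.integer(rownames(s)), ] <- s
  out
}

# dihedral angles and (optionally) their Cartesian derivatives for a set of
# quadruples; standard cross-product formulation
torsion_terms <- function(xyz, quad, gradient = FALSE) {
  b1 <- xyz[quad[, 2L], , drop = FALSE] - xyz[quad[, 1L], , drop = FALSE]
  b2 <- xyz[quad[, 3L], , drop = FALSE] - xyz[quad[, 2L], , drop = FALSE]
  b3 <- xyz[quad[, 4L], , drop = FALSE] - xyz[quad[, 3L], , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  phi <- atan2(rowSums(cross(n1, n2) * b2) / b2n, rowSums(n1 * n2))
  out <- list(phi = phi)
  if (gradient) {
    n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
    dphi1 <- -n1 * (b2n / n1sq)
    dphi4 <-  n2 * (b2n / n2sq)
    f12 <- rowSums(b1 * b2) / b2n^2
    f32 <- rowSums(b3 * b2) / b2n^2
    dphi2 <- -dphi1 * (1 + f12) + dphi4 * f32
    dphi3 <- dphi1 * f12 - dphi4 * (1 + f32)
    out$dphi <- list(dphi1, dphi2, dphi3, dphi4)
  }
  out
}

#' Toy-potential single point on a system
#'
#' @param system a [mol_system()]
#' @param gradient also return the analytic gradient (attached as the
#'   `gradient` attribute of the result)?
#' @param config a [backend_config()] supplying toy parameters
#' @param topo optional precomputed [toy_topology()] (reused across calls on
#'   the same connectivity)
#' @return an `energy_result`
#' @export
toy_energy <- function(system, gradient = FALSE, config = backend_config(),
                       topo = NULL) {
  t0 <- proc.time()[["elapsed"]]
  xyz <- sys_coords(system)
  clash <- min_pair_distance(xyz)
  if (!is.na(clash) && clash < 0.3) {
    return(energy_result(status = "failed",
                         seconds = proc.time()[["elapsed"]] - t0,
                         reason = sprintf("overlapping atoms (min pair distance %.3f A)",
                                          clash)))
  }
  if (is.null(topo)) topo <- toy_topology(system)
  ev <- toy_eval(xyz, topo, params = config$toy, gradient = gradient)
  res <- energy_result(total = ev$total, gas = ev$gas,
                       solvation = ev$solvation,
                       seconds = proc.time()[["elapsed"]] - t0)
  if (gradient) attr(res, "gradient") <- ev$grad
  res
}

min_pair_distance <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(NA_real_)
  min(stats::dist(xyz))
}

# --- engine adapter ---------------------------------------------------------

#' Write a semi-empirical engine job file
#'
#' Produces the input dialect of a MOPAC-style program: a keyword header
#' naming the PM7 Hamiltonian, the single-SCF directive, the COSMO solvent
#' keyword with the configured permittivity and the total charge, followed by
#' Cartesian coordinates with all optimization flags 0 (single point). The
#' linear-scaling keyword (MOZYME) is added for systems above 300 atoms.
#' Output is byte-stable for fixed input and configuration.
#'
#' @param system a [mol_system()] with formal charges assigned
#' @param config a [backend_config()]
#' @return the job text as a single character scalar
#' @export
write_engine_input <- function(system, config = backend_config("engine")) {
  if (is.null(system$charge) || is.na(system$charge))
    stop("system charge is not set")
  kw <- c("PM7",
          if (nrow(system$atoms) > 300L) "MOZYME",
          "1SCF",
          sprintf("EPS=%.2f", config$eps),
          sprintf("CHARGE=%d", system$charge),
          "GEO-OK",
          config$keywords)
  a <- system$atoms
  geom <- sprintf("%-2s %15.8f 0 %15.8f 0 %15.8f 0",
                  a$element, a$x, a$y, a$z)
  paste(c(paste(kw, collapse = " "),
          sprintf("single point, %d atoms", nrow(a)),
          "", geom, ""),
        collapse = "\n")
}

#' Parse a semi-empirical engine output stream
#'
#' Extracts the final heat of formation (kcal/mol, the total energy including
#' the continuum solvation contribution), the dielectric solvation energy
#' (converted from eV) and the solvent-accessible surface area when present.
#' An output lacking the normal-termination marker is reported as `failed`;
#' no condition raises an error, so one broken job never aborts a screen.
#'
#' @param text character vector of output lines, or a single string
#' @return an `energy_result`
#' @export
parse_engine_output <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  done <- any(grepl("== MOPAC DONE ==", lines, fixed = TRUE))
  grab <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    rhs <- sub("^[^=]*=", "", hit[1L])
    num <- regmatches(rhs, regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                   rhs))
    if (!length(num)) NA_real_ else as.numeric(num)
  }
  hof <- grab("FINAL HEAT OF FORMATION")
  if (!done || is.na(hof)) {
    return(energy_result(status = "failed",
                         reason = if (!done) "no normal-termination marker"
                                  else "heat of formation not found"))
  }
  solv_ev <- grab("DIELECTRIC ENERGY")
  solv <- if (is.na(solv_ev)) 0 else solv_ev * EV_TO_KCAL
  sasa <- grab("COSMO AREA")
  energy_result(total = hof, gas = hof - solv, solvation = solv, sasa = sasa)
}

engine_single_point <- function(system, config) {
  t0 <- proc.time()[["elapsed"]]
  job <- write_engine_input(system, config)
  dir.create(config$scratch, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(config$scratch,
                    sprintf("job_%s", substr(digest_text(job), 1, 12)))
  writeLines(job, paste0(stem, ".mop"))
  if (!nzchar(config$engine_cmd)) {
    return(energy_result(status = "failed",
                         seconds = proc.time()[["elapsed"]] - t0,
                         reason = paste0("engine not configured; job written to ",
                                         stem, ".mop")))
  }
  status <- tryCatch(
    system2(config$engine_cmd, args = paste0(stem, ".mop"),
            stdout = FALSE, stderr = FALSE, timeout = config$timeout),
    error = function(e) -1L, warning = function(w) -1L)
  outfile <- paste0(stem, ".out")
  if (!file.exists(outfile)) {
    return(energy_result(status = "failed",
                         seconds = proc.time()[["elapsed"]] - t0,
                         reason = "engine produced no output (timeout or crash)"))
  }
  res <- parse_engine_output(readLines(outfile, warn = FALSE))
  res$seconds <- proc.time()[["elapsed"]] - t0
  res
}

# small stable polynomial text hash (hex) for cache keys and scratch names
digest_text <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  m <- 2147483629
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 65599 + b) %% m
    h2 <- (h2 * 31 + b + 7) %% m
  }
  sprintf("%08x%08x", h1, h2)
}
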