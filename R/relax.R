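# Restrained local relaxation of docked complexes and generation of the
# unbound (free-state) protein and ligand references. Minimization is
# all-Cartesian with a frozen shell: only residues near the docked library
# (plus the ligand) move; everything else is held fixed.

#' Movable-atom region for complex relaxation
#'
#' Residues with any heavy atom within `cutoff` (default 4 A) of any heavy
#' atom of any docked pose in the library are free to move; the rest of the
#' receptor is frozen. Ligand atoms are always movable (handled by
#' [restrained_relax()]).
#'
#' @param receptor a [mol_system()] (typically the reduced system cluster)
#' @param poses list of `docked_pose` or `molsys`
#' @param cutoff heavy-atom distance threshold, Angstrom (default 4)
#' @return logical vector over receptor atoms: TRUE = movable
#' @export
free_region <- function(receptor, poses, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  if (!length(poses)) stop("empty pose list")
  pose_xyz <- do.call(rbind, lapply(poses, function(p) {
    s <- if (inherits(p, "docked_pose")) p$system else p
    as.matrix(s$atoms[s$atoms$heavy, c("x", "y", "z"), drop = FALSE])
  }))
  d <- residue_min_dist(receptor, pose_xyz, classes = "protein")
  free_keys <- names(d)[d <= cutoff]
  a <- receptor$atoms
  a$class == "protein" & residue_key(a) %in% free_keys
}

# L-BFGS-B minimization of the toy potential over a movable subset, with an
# optional harmonic positional restraint on movable heavy atoms
minimize_cartesian <- function(system, config, movable,
                               restraint_weight = 0, x_ref = NULL,
                               tol = 1e-3, maxit = 500L) {
  if (config$backend != "toy")
    stop("Cartesian minimization needs a gradient-capable backend (toy)")
  xyz <- sys_coords(system)
  topo <- toy_topology(system)
  mov <- which(movable)
  if (!length(mov)) return(list(system = system,
                                energy = toy_eval(xyz, topo, config$toy)$total,
                                converged = TRUE))
  if (is.null(x_ref)) x_ref <- xyz
  heavy <- system$atoms$heavy
  restrained <- movable & heavy  # hydrogens are never restrained
  fn <- function(par) {
    x <- xyz; x[mov, ] <- matrix(par, ncol = 3L)
    e <- toy_eval(x, topo, config$toy)$total
    if (restraint_weight > 0) {
      d <- x[restrained, , drop = FALSE] - x_ref[restrained, , drop = FALSE]
      e <- e + restraint_weight * sum(d^2)
    }
    e
  }
  gr <- function(par) {
    x <- xyz; x[mov, ] <- matrix(par, ncol = 3L)
    g <- toy_eval(x, topo, config$toy, gradient = TRUE)$grad
    if (restraint_weight > 0) {
      g[restrained, ] <- g[restrained, ] +
        2 * restraint_weight * (x[restrained, , drop = FALSE] -
                                x_ref[restrained, , drop = FALSE])
    }
    as.numeric(g[mov, , drop = FALSE])
  }
  fit <- stats::optim(as.numeric(xyz[mov, , drop = FALSE]), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = tol,
                                     factr = 1e3))
  xyz[mov, ] <- matrix(fit$par, ncol = 3L)
  list(system = sys_set_coords(system, xyz),
       energy = toy_eval(xyz, topo, config$toy)$total,
       converged = fit$convergence %in% c(0L, 1L))
}

#' Restrained relaxation of a docked complex
#'
#' Runs the cycle schedule of local energy minimizations under a harmonic
#' positional restraint on movable heavy atoms, with the restraint weight
#' stepped down each cycle -- default 50, 10, 5, 1, 0 kcal/mol/A^2, the last
#' cycle fully unrestrained. The restraint reference is reset to the
#' cycle-start coordinates at each cycle (set `reset_reference = FALSE` to
#' keep the original structure as the reference throughout). Frozen atoms
#' never move; hydrogens move but are never restrained.
#'
#' @param complex a [mol_system()] holding pocket + ligand atoms
#' @param config a [backend_config()] (toy backend required)
#' @param movable logical vector over complex atoms (from [free_region()],
#'   extended to ligand atoms automatically)
#' @param weights restraint schedule, kcal/mol/A^2
#' @param tol gradient-norm convergence tolerance, kcal/mol/A (default 1e-3)
#' @param maxit iteration cap per cycle (default 500)
#' @param reset_reference reset the restraint reference each cycle?
#' @return list with `system` (relaxed), `cycle_energies` (unrestrained
#'   energy at each cycle end), `status` (`"converged"` or `"failed"`)
#' @export
restrained_relax <- function(complex, config = backend_config(),
                             movable = NULL,
                             weights = c(50, 10, 5, 1, 0),
                             tol = 1e-3, maxit = 500L,
                             reset_reference = TRUE) {
  check <- single_point(complex, config)
  if (check$status != "converged") {
    return(list(system = complex, cycle_energies = numeric(),
                status = "failed", reason = check$reason))
  }
  if (is.null(movable)) movable <- rep(TRUE, nrow(complex$atoms))
  movable <- movable | complex$atoms$class == "ligand"
  cur <- complex
  x_ref0 <- sys_coords(complex)
  energies <- numeric(0)
  for (w in weights) {
    x_ref <- if (reset_reference) sys_coords(cur) else x_ref0
    step <- minimize_cartesian(cur, config, movable,
                               restraint_weight = w, x_ref = x_ref,
                               tol = tol, maxit = maxit)
    cur <- step$system
    energies <- c(energies, step$energy)
  }
  list(system = cur, cycle_energies = energies, status = "converged")
}

#' Unbound (free-state) reference of an isolated species
#'
#' Unrestrained local minimization of the isolated protein cluster or ligand
#' starting from the given conformation. The resulting backend energy is the
#' free-state G(X) entering the deformation penalty; the protein free state
#' is computed once per target and cached by the scoring driver.
#'
#' @param system isolated [mol_system()] (P or L)
#' @param config a [backend_config()] (toy backend required)
#' @param tol,maxit minimizer controls
#' @return list with `system` (minimized), `energy` (kcal/mol), `status`
#' @export
unbound_state <- function(system, config = backend_config(),
                          tol = 1e-3, maxit = 500L) {
  check <- single_point(system, config)
  if (check$status != "converged") {
    return(list(system = system, energy = NA_real_,
                status = "failed", reason = check$reason))
  }
  step <- minimize_cartesian(system, config,
                             movable = rep(TRUE, nrow(system$atoms)),
                             tol = tol, maxit = maxit)
  list(system = step$system, energy = step$energy, status = "converged")
}
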