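# Ligand conformational entropy on binding: DS = -R ln(Omega), assuming the
# bound molecule occupies a single conformation. Omega is estimated either
# from the rotatable-bond count (3^N rotamers) or by Monte-Carlo torsional
# sampling with local minimization, counting distinct low-energy conformers.

R_GAS <- 1.987e-3  # kcal / (mol K)

#' Count freely rotatable bonds
#'
#' A bond is rotatable when it is a single bond between two heavy atoms, not
#' part of a ring, each end carries at least one further heavy-atom
#' neighbour, and it is not an amide C-N bond (carbonyl carbon to nitrogen).
#'
#' @param system a [mol_system()]
#' @return list with `n` (the count) and `bonds` (data.frame `i`, `j` of the
#'   rotatable bonds, suitable for [sample_conformers()])
#' @export
count_rotatable_bonds <- function(system) {
  b <- system$bonds
  a <- system$atoms
  if (!nrow(b)) return(list(n = 0L, bonds = empty_bonds()[, c("i", "j")]))
  nbrs <- adjacency(system)
  heavy_deg <- vapply(nbrs, function(nb) sum(a$heavy[nb]), 0L)
  keep <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (b$order[k] != 1L) next
    if (!a$heavy[i] || !a$heavy[j]) next
    # each end needs a further heavy neighbour beyond the bond itself
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next
    if (in_ring(system, k)) next
    if (is_amide(a, nbrs, b, i, j)) next
    keep[k] <- TRUE
  }
  list(n = sum(keep), bonds = b[keep, c("i", "j"), drop = FALSE])
}

adjacency <- function(system) {
  n <- nrow(system$atoms)
  nbrs <- vector("list", n)
  b <- system$bonds
  for (k in seq_len(nrow(b))) {
    nbrs[[b$i[k]]] <- c(nbrs[[b$i[k]]], b$j[k])
    nbrs[[b$j[k]]] <- c(nbrs[[b$j[k]]], b$i[k])
  }
  nbrs
}

# bond k is in a ring iff its endpoints stay connected once it is removed
in_ring <- function(system, k) {
  b <- system$bonds[-k, , drop = FALSE]
  i <- system$bonds$i[k]; j <- system$bonds$j[k]
  length(intersect(graph_component(b, i, nrow(system$atoms)), j)) > 0L
}

graph_component <- function(bonds, start, n) {
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    nbrs[[bonds$i[k]]] <- c(nbrs[[bonds$i[k]]], bonds$j[k])
    nbrs[[bonds$j[k]]] <- c(nbrs[[bonds$j[k]]], bonds$i[k])
  }
  seen <- logical(n); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    new <- nbrs[[v]][!seen[nbrs[[v]]]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  which(seen)
}

is_amide <- function(a, nbrs, b, i, j) {
  pair_is <- function(ci, ni) {
    if (a$element[ci] != "C" || a$element[ni] != "N") return(FALSE)
    # carbonyl: the carbon holds a double bond to oxygen
    dbl <- b$i == ci | b$j == ci
    any(b$order[dbl] == 2L &
          a$element[ifelse(b$i[dbl] == ci, b$j[dbl], b$i[dbl])] == "O")
  }
  pair_is(i, j) || pair_is(j, i)
}

#' Rotamer-count conformation estimate
#'
#' Each free torsional bond is granted three rotational states, so
#' \eqn{\Omega = 3^N}. Known to over-count low-energy conformers, hence the
#' Monte-Carlo estimator is the scoring default.
#'
#' @param n_rotatable number of rotatable bonds (integer >= 0)
#' @return Omega (numeric)
#' @export
omega_rot <- function(n_rotatable) {
  stopifnot(n_rotatable >= 0, n_rotatable == round(n_rotatable))
  3^n_rotatable
}

#' Monte-Carlo torsional sampling with local minimization
#'
#' Metropolis walk in the torsion space of the molecule's rotatable bonds:
#' each step perturbs one torsion uniformly in (-180, 180] degrees and
#' accepts or rejects by the Metropolis criterion; after every accepted move
#' all torsions are locally minimized and the minimized conformer is
#' recorded. Deterministic for a fixed seed; bond lengths and angles stay
#' frozen during the walk.
#'
#' @param system a [mol_system()] of the isolated ligand
#' @param config a [backend_config()] supplying the energy function
#' @param steps number of MC steps (default 1000 per rotatable bond)
#' @param temperature Metropolis temperature in K (default 300)
#' @param seed RNG seed (default 0)
#' @return list with `conformers` (each: `torsions` in degrees, `energy`),
#'   `rotatable` (the bond table) and `n_rotatable`
#' @export
sample_conformers <- function(system, config = backend_config(),
                              steps = NULL, temperature = 300, seed = 0) {
  rot <- count_rotatable_bonds(system)
  if (rot$n == 0L) {
    e <- single_point(system, config)
    return(list(conformers = list(list(torsions = numeric(), energy = e$total)),
                rotatable = rot$bonds, n_rotatable = 0L))
  }
  if (is.null(steps)) steps <- 1000L * rot$n
  machinery <- torsion_machinery(system, rot$bonds)
  topo <- toy_topology(system)
  engine_backend <- config$backend != "toy"
  energy_at <- function(tor) {
    xyz <- machinery$set(tor)
    if (engine_backend) single_point(sys_set_coords(system, xyz), config)$total
    else toy_eval(xyz, topo, params = config$toy)$total
  }
  # analytic torsion-space gradient via the Cartesian gradient and the
  # rotation chain rule dx_i/dphi = u x (x_i - p) over the moving set
  grad_at <- function(tor) {
    xyz <- machinery$set(tor)
    g <- toy_eval(xyz, topo, params = config$toy, gradient = TRUE)$grad
    vapply(machinery$specs, function(s) {
      p <- xyz[s$quad[2L], ]
      u <- xyz[s$quad[3L], ] - p
      u <- u / sqrt(sum(u^2))
      rel <- sweep(xyz[s$moving, , drop = FALSE], 2L, p)
      cr <- cbind(u[2L] * rel[, 3L] - u[3L] * rel[, 2L],
                  u[3L] * rel[, 1L] - u[1L] * rel[, 3L],
                  u[1L] * rel[, 2L] - u[2L] * rel[, 1L])
      sum(g[s$moving, , drop = FALSE] * cr) * pi / 180
    }, 0)
  }
  # parscale in degrees-per-radian conditions BFGS properly: torsional
  # curvature per degree^2 is tiny and stalls the default unit scaling
  descend <- function(tor, maxit) {
    ctl <- list(maxit = maxit, reltol = 1e-9,
                parscale = rep(180 / pi, length(tor)))
    if (engine_backend) {
      stats::optim(tor, energy_at, method = "BFGS", control = ctl)
    } else {
      stats::optim(tor, energy_at, grad_at, method = "BFGS", control = ctl)
    }
  }
  # local minimization with escape from torsional saddle points (where the
  # gradient vanishes but the point is not a minimum); always returns the
  # result of a full descent
  minimize_tor <- function(tor) {
    cur <- tor; val <- NA_real_
    for (round in 1:4) {
      fit <- descend(cur, 60L)
      cur <- fit$par; val <- fit$value
      if (round == 4L) break
      probes <- do.call(rbind, lapply(seq_along(cur), function(k) {
        up <- cur; up[k] <- up[k] + 20
        dn <- cur; dn[k] <- dn[k] - 20
        rbind(up, dn)
      }))
      pe <- apply(probes, 1L, energy_at)
      if (min(pe) >= val - 1e-8) break
      cur <- probes[which.min(pe), ]
    }
    list(torsions = wrap_angle(cur), energy = val)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  kT <- R_GAS * temperature
  start <- machinery$measure()
  first <- minimize_tor(start)
  conformers <- list(first)
  minima <- list(first)  # distinct minima found so far, for basin lookup
  locate <- function(tor) {
    # a short descent followed by a match against known minima avoids
    # re-minimizing a basin that has already been fully resolved
    part <- tryCatch(descend(tor, 8L), error = function(e) NULL)
    if (is.null(part) || !is.finite(part$value)) return(NULL)
    for (m in minima) {
      if (max(circular_diff(part$par, m$torsions)) <= 15) return(m)
    }
    cand <- tryCatch(minimize_tor(part$par), error = function(e) NULL)
    if (is.null(cand) || !is.finite(cand$energy)) return(NULL)
    if (!any(vapply(minima, function(m)
      max(circular_diff(cand$torsions, m$torsions)) <= 15, TRUE)))
      minima[[length(minima) + 1L]] <<- cand
    cand
  }
  cur_tor <- start
  cur_e <- energy_at(start)
  failed <- 0L
  for (step in seq_len(steps)) {
    prop <- cur_tor
    prop[sample.int(length(prop), 1L)] <- stats::runif(1L, -180, 180)
    prop_e <- tryCatch(energy_at(prop), error = function(e) NA_real_)
    if (!is.finite(prop_e)) { failed <- failed + 1L; next }
    if (prop_e <= cur_e || stats::runif(1L) < exp((cur_e - prop_e) / kT)) {
      cur_tor <- prop; cur_e <- prop_e
      cand <- locate(prop)
      if (is.null(cand)) { failed <- failed + 1L; next }
      conformers[[length(conformers) + 1L]] <- cand
    }
  }
  if (failed) message(failed, " sampling step(s) skipped on backend failure")
  list(conformers = conformers, rotatable = rot$bonds, n_rotatable = rot$n)
}

# torsion measurement + rebuild closures for a set of rotatable bonds
torsion_machinery <- function(system, rot_bonds) {
  xyz0 <- sys_coords(system)
  nbrs <- adjacency(system)
  a <- system$atoms
  n <- nrow(a)
  specs <- lapply(seq_len(nrow(rot_bonds)), function(k) {
    bi <- rot_bonds$i[k]; ci <- rot_bonds$j[k]
    pick <- function(at, excl) {
      cand <- setdiff(nbrs[[at]], excl)
      heavy <- cand[a$heavy[cand]]
      if (length(heavy)) min(heavy) else min(cand)
    }
    ai <- pick(bi, ci); di <- pick(ci, bi)
    # atoms on the d-side move when this torsion turns
    side <- graph_component(
      system$bonds[!(system$bonds$i %in% c(bi, ci) &
                     system$bonds$j %in% c(bi, ci)), , drop = FALSE],
      ci, n)
    list(quad = c(ai, bi, ci, di), moving = setdiff(side, ci))
  })
  measure_one <- function(xyz, quad) {
    torsion_terms(xyz, matrix(quad, nrow = 1L))$phi * 180 / pi
  }
  measure <- function(xyz = xyz0) {
    vapply(specs, function(s) measure_one(xyz, s$quad), 0)
  }
  base <- measure(xyz0)
  # apply parent rotations before rotations nested inside their moving set,
  # so each target angle lands exactly (larger moving sets first)
  ord <- order(-vapply(specs, function(s) length(s$moving), 0L))
  set <- function(tor) {
    xyz <- xyz0
    for (k in ord) {
      s <- specs[[k]]
      delta <- (tor[k] - base[k]) * pi / 180
      if (abs(delta) < 1e-12) next
      xyz[s$moving, ] <- rotate_about_axis(xyz[s$moving, , drop = FALSE],
                                           xyz[s$quad[2L], ], xyz[s$quad[3L], ],
                                           delta)
    }
    xyz
  }
  list(measure = measure, set = set, specs = specs, base = base)
}

# Rodrigues rotation of points about the axis through p1 -> p2 by angle theta
rotate_about_axis <- function(pts, p1, p2, theta) {
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  ct <- cos(theta); st <- sin(theta)
  rel <- sweep(pts, 2L, p1)
  dotu <- drop(rel %*% u)
  crossu <- cbind(u[2L] * rel[, 3L] - u[3L] * rel[, 2L],
                  u[3L] * rel[, 1L] - u[1L] * rel[, 3L],
                  u[1L] * rel[, 2L] - u[2L] * rel[, 1L])
  rot <- rel * ct + crossu * st + outer(dotu * (1 - ct), u)
  sweep(rot, 2L, p1, `+`)
}

wrap_angle <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

circular_diff <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}

#' Count distinct low-energy conformers
#'
#' Keeps conformers within `window` kcal/mol of the sampled minimum
#' (default 3), then deduplicates: two conformers are the same state when no
#' torsion differs by more than `distinct_threshold` degrees (circular).
#' All surviving conformers are weighted equally.
#'
#' @param conformers list from [sample_conformers()] (or its `conformers`
#'   element)
#' @param window energy window above the minimum, kcal/mol (default 3)
#' @param distinct_threshold torsion-difference threshold in degrees
#'   (default 30)
#' @return Omega, the number of distinct accessible conformations (>= 1)
#' @export
omega_conf <- function(conformers, window = 3.0, distinct_threshold = 30) {
  if (!is.null(conformers$conformers)) conformers <- conformers$conformers
  stopifnot(length(conformers) >= 1L)
  e <- vapply(conformers, `[[`, 0, "energy")
  keep <- which(e - min(e) <= window)
  keep <- keep[order(e[keep])]
  reps <- list()
  for (k in keep) {
    tor <- conformers[[k]]$torsions
    dup <- any(vapply(reps, function(r)
      length(tor) == 0L || max(circular_diff(tor, r)) <= distinct_threshold,
      TRUE))
    if (!dup || !length(reps)) reps[[length(reps) + 1L]] <- tor
  }
  length(reps)
}

#' Entropy term from a conformation count
#'
#' \deqn{\Delta S = -R \ln \Omega, \qquad -T\Delta S = R T \ln \Omega}
#' with R = 1.987e-3 kcal/(mol K). Omega = 1 gives exactly zero; the penalty
#' is nonnegative and grows logarithmically with the conformation count.
#'
#' @param omega number of free-state conformations (>= 1)
#' @param T temperature in K (default 298.15)
#' @param method label recorded in the estimate (`"rot"` or `"conf"`)
#' @param n_rotatable rotatable-bond count (metadata)
#' @param seed sampling seed (metadata)
#' @return an `entropy_estimate`: list with `omega`, `method`, `n_rotatable`,
#'   `dS` (kcal/mol/K), `mTdS` (-T dS, kcal/mol), `T`, `seed`
#' @export
entropy_term <- function(omega, T = 298.15, method = "conf",
                         n_rotatable = NA_integer_, seed = NA_integer_) {
  stopifnot(omega >= 1, T > 0)
  dS <- -R_GAS * log(omega)
  structure(list(omega = omega, method = method, n_rotatable = n_rotatable,
                 dS = dS, mTdS = -T * dS, T = T, seed = seed),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> method=%s Omega=%g N=%s  -TdS = %.4f kcal/mol\n",
              x$method, x$omega,
              ifelse(is.na(x$n_rotatable), "?", x$n_rotatable), x$mTdS))
  invisible(x)
}

#' Full ligand entropy estimate
#'
#' Convenience wrapper: counts rotatable bonds and evaluates the configured
#' estimator. The Monte-Carlo estimator (`"conf"`) is the scoring default;
#' the rotamer count (`"rot"`) is available but known to over-estimate the
#' penalty.
#'
#' @param system isolated ligand [mol_system()]
#' @param method `"conf"` (default) or `"rot"`
#' @param config backend for sampling energies
#' @param T temperature (K)
#' @param seed,steps,temperature,window,distinct_threshold sampling controls
#'   passed to [sample_conformers()] / [omega_conf()]
#' @return an `entropy_estimate`
#' @export
ligand_entropy <- function(system, method = c("conf", "rot"),
                           config = backend_config(), T = 298.15,
                           seed = 0, steps = NULL, temperature = 300,
                           window = 3.0, distinct_threshold = 30) {
  method <- match.arg(method)
  rot <- count_rotatable_bonds(system)
  if (method == "rot" || rot$n == 0L) {
    omega <- omega_rot(rot$n)
    return(entropy_term(omega, T = T, method = method,
                        n_rotatable = rot$n, seed = seed))
  }
  samp <- sample_conformers(system, config = config, steps = steps,
                            temperature = temperature, seed = seed)
  omega <- omega_conf(samp, window = window,
                      distinct_threshold = distinct_threshold)
  if (omega > omega_rot(rot$n))
    message("MC conformer count ", omega, " exceeds rotamer bound 3^",
            rot$n, " (frustrated landscape)")
  entropy_term(omega, T = T, method = "conf",
               n_rotatable = rot$n, seed = seed)
}

#' Write a per-molecule entropy report
#' @param estimates named list of `entropy_estimate` (names = state ids)
#' @param path output TSV path
#' @export
write_entropy_report <- function(estimates, path) {
  rows <- do.call(rbind, lapply(names(estimates), function(id) {
    e <- estimates[[id]]
    data.frame(state_id = id, n_rotatable = e$n_rotatable, method = e$method,
               omega = e$omega, dS = e$dS, mTdS = e$mTdS, seed = e$seed)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
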