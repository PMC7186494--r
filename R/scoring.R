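# Assembly of the QM docking score (QMDS) variants from single-point
# energies, deformation penalties and the entropy term:
#
#   QMDS            = dG_o - T dS                      (variants 1, 2)
#   QMDS (with "d") = dG_o + dG_conf(P) + dG_conf(L) - T dS
#
# where dG_o = G(PL) - G_o(P) - G_o(L) is evaluated with all species in the
# conformation of the docked complex, and dG_conf(X) = G_o(X) - G(X) is the
# strain of X relative to its relaxed free state. The two forms are
# algebraically identical to G(PL) - G(P) - G(L) - T dS. Variant 1 scores
# the raw docked complex; variant 2 first relaxes it under the restraint
# schedule. Scores are rankings, not absolute binding free energies.

#' The four QMDS score variants
#'
#' `"QMDS1"`/`"QMDS1d"` score the raw docked complex, `"QMDS2"`/`"QMDS2d"`
#' the relaxed one; the `d` suffix adds the explicit protein and ligand
#' deformation penalties.
#' @export
QMDS_VARIANTS <- c("QMDS1", "QMDS1d", "QMDS2", "QMDS2d")

#' Docked-conformation interaction energy
#'
#' \deqn{\Delta G_o = G(PL) - G_o(P) - G_o(L)} with every term evaluated in
#' the conformation taken from the docked complex.
#'
#' @param g_pl,g_op,g_ol energies in kcal/mol
#' @return dG_o (kcal/mol)
#' @export
delta_g_o <- function(g_pl, g_op, g_ol) g_pl - g_op - g_ol

#' Deformation (strain) penalty of one species
#'
#' \deqn{\Delta G_{conf}(X) = G_o(X) - G(X)}: the energy of isolated X in its
#' bound-complex conformation minus its relaxed free-state energy.
#' Nonnegative whenever the free state descends from the bound conformation.
#'
#' @param g_ox energy of X in the docked-complex conformation (kcal/mol)
#' @param g_x energy of X in its relaxed free state (kcal/mol)
#' @return dG_conf(X) (kcal/mol)
#' @export
deformation <- function(g_ox, g_x) g_ox - g_x

#' Assemble one score record from components
#'
#' @param components list with entries `g_pl`, `g_op`, `g_ol`, `mTdS`, and
#'   for the deformation ("d") variants also `g_p`, `g_l`. A missing or
#'   non-finite required component yields a failed record, never a number.
#' @param variant one of `"QMDS1"`, `"QMDS1d"`, `"QMDS2"`, `"QMDS2d"`
#' @param state_id,parent_id identifiers carried into the record
#' @return one-row data.frame (a score record) with the component columns
#'   and the assembled `qmds` value, or NA plus `status = "failed"`
#' @export
assemble <- function(components, variant, state_id = NA_character_,
                     parent_id = NA_character_) {
  stopifnot(variant %in% QMDS_VARIANTS)
  with_deformation <- grepl("d$", variant)
  need <- c("g_pl", "g_op", "g_ol", "mTdS",
            if (with_deformation) c("g_p", "g_l"))
  get_num <- function(nm) {
    v <- components[[nm]]
    if (is.null(v) || !is.finite(v)) NA_real_ else v
  }
  vals <- stats::setNames(lapply(
    c("g_pl", "g_op", "g_ol", "g_p", "g_l", "mTdS"), get_num),
    c("g_pl", "g_op", "g_ol", "g_p", "g_l", "mTdS"))
  ok <- all(vapply(need, function(nm) is.finite(vals[[nm]]), TRUE))
  dgo <- delta_g_o(vals$g_pl, vals$g_op, vals$g_ol)
  dgp <- deformation(vals$g_op, vals$g_p)
  dgl <- deformation(vals$g_ol, vals$g_l)
  qmds <- if (!ok) NA_real_
          else if (with_deformation) dgo + dgp + dgl + vals$mTdS
          else dgo + vals$mTdS
  data.frame(state_id = state_id, parent_id = parent_id, variant = variant,
             g_pl = vals$g_pl, g_op = vals$g_op, g_ol = vals$g_ol,
             g_p = vals$g_p, g_l = vals$g_l,
             dGo = if (ok) dgo else NA_real_,
             dGconfP = if (ok && with_deformation) dgp else NA_real_,
             dGconfL = if (ok && with_deformation) dgl else NA_real_,
             mTdS = vals$mTdS,
             qmds = qmds,
             status = if (ok) "converged" else "failed",
             stringsAsFactors = FALSE)
}

#' Score a docked library with the QMDS variants
#'
#' End-to-end per-target driver: builds the reduced binding-site cluster
#' (union 8 A selection over the whole library, defragmented and capped),
#' evaluates the required single points through the configured backend with
#' component caching, estimates the ligand entropy term per state, optionally
#' relaxes each complex for the variant-2 scores, and assembles all requested
#' variants. The pocket docked-conformation energy G_o(P) and the pocket free
#' state G(P) are per-target constants, computed once and reused; a failed
#' backend job fails only the records that need it.
#'
#' @param receptor a [mol_system()] with formal charges assigned (and, if
#'   wanted, waters/ions already filtered by [select_environment()])
#' @param poses list of `docked_pose`
#' @param config a [backend_config()]
#' @param variants subset of `c("QMDS1","QMDS1d","QMDS2","QMDS2d")`
#' @param cutout_cutoff residue-selection threshold, A (default 8)
#' @param free_cutoff movable-region threshold for relaxation, A (default 4)
#' @param entropy_method `"conf"` (default) or `"rot"`
#' @param entropy_T temperature for the -T dS term, K
#' @param entropy_seed seed for conformer sampling
#' @param max_gap,min_fragment anti-fragmentation controls ([defragment()])
#' @param reduced optional precomputed `reduced_system` (skips the cutout)
#' @return data.frame of score records, one row per pose and variant, plus
#'   attributes `reduced` (the cluster) and `entropy` (per-state estimates)
#' @export
score_library <- function(receptor, poses, config = backend_config(),
                          variants = QMDS_VARIANTS,
                          cutout_cutoff = 8.0, free_cutoff = 4.0,
                          entropy_method = c("conf", "rot"),
                          entropy_T = 298.15, entropy_seed = 0,
                          max_gap = 2L, min_fragment = 2L,
                          reduced = NULL) {
  entropy_method <- match.arg(entropy_method)
  stopifnot(all(variants %in% QMDS_VARIANTS), length(poses) > 0)
  if (is.null(reduced)) {
    selected <- residues_within(receptor, poses, cutout_cutoff)
    selected <- defragment(selected, receptor, max_gap = max_gap,
                           min_fragment = min_fragment)
    reduced <- build_reduced(receptor, selected)
  }
  pocket <- reduced$system
  np <- nrow(pocket$atoms)

  # single-point cache keyed by geometry+charge+backend fingerprint
  cache <- new.env(hash = TRUE)
  sp <- function(sys) {
    key <- digest_text(paste(c(sprintf("%.6f", sys_coords(sys)),
                               sys$atoms$charge, config$backend,
                               sprintf("%.4f", unlist(config$toy))),
                             collapse = ","))
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    res <- single_point(sys, config)
    assign(key, res, envir = cache)
    res
  }

  g_op <- sp(pocket)                       # per-target constant (variant 1)
  need_relax <- any(grepl("^QMDS2", variants))
  need_deform <- any(grepl("d$", variants))
  g_p <- NULL
  if (need_deform) g_p <- unbound_state(pocket, config)
  movable_pocket <- if (need_relax) free_region(pocket, poses, free_cutoff)

  entropy <- list()
  records <- vector("list", length(poses) * length(variants))
  ri <- 0L
  for (pose in poses) {
    L <- pose$system
    ent <- entropy[[pose$state_id]]
    if (is.null(ent)) {
      ent <- ligand_entropy(L, method = entropy_method, config = config,
                            T = entropy_T, seed = entropy_seed)
      entropy[[pose$state_id]] <- ent
    }
    g_ol <- sp(L)
    g_l <- if (need_deform) unbound_state(L, config)
    complex1 <- sys_combine(pocket, L)
    g_pl1 <- sp(complex1)
    comp1 <- list(g_pl = g_pl1$total, g_op = g_op$total, g_ol = g_ol$total,
                  g_p = if (need_deform) g_p$energy,
                  g_l = if (need_deform) g_l$energy,
                  mTdS = ent$mTdS)
    comp2 <- NULL
    if (need_relax) {
      if (g_pl1$status == "converged") {
        movable <- c(movable_pocket, rep(TRUE, nrow(L$atoms)))
        rel <- restrained_relax(complex1, config, movable = movable)
        if (rel$status == "converged") {
          rp <- sys_subset(rel$system, seq_len(np))
          rl <- sys_subset(rel$system, np + seq_len(nrow(L$atoms)))
          comp2 <- list(g_pl = sp(rel$system)$total, g_op = sp(rp)$total,
                        g_ol = sp(rl)$total,
                        g_p = if (need_deform) g_p$energy,
                        g_l = if (need_deform) g_l$energy,
                        mTdS = ent$mTdS)
        }
      }
      if (is.null(comp2)) comp2 <- list(mTdS = ent$mTdS)  # failed relaxation
    }
    for (v in variants) {
      ri <- ri + 1L
      records[[ri]] <- assemble(if (grepl("^QMDS2", v)) comp2 else comp1,
                                v, pose$state_id, pose$parent_id)
      records[[ri]]$is_ligand <- pose$is_ligand
    }
  }
  out <- do.call(rbind, records[seq_len(ri)])
  rownames(out) <- NULL
  attr(out, "reduced") <- reduced
  attr(out, "entropy") <- entropy
  out
}

#' Write score records as TSV
#' @param records data.frame from [score_library()]
#' @param path output path
#' @export
write_scores <- function(records, path) {
  utils::write.table(records, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
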