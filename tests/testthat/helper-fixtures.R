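# Shared fixture builders: all constructed in code, nothing downloaded.

# zig-zag heavy-atom chain with tetrahedral angles and C-C bonds at the toy
# reference length; n-1 bonds, n-3 proper torsions
chain_molecule <- function(n, element = "C", charges = rep(0L, n)) {
  xyz <- matrix(0, n, 3L)
  if (n > 1L) xyz[2L, ] <- c(1.54, 0, 0)
  ang <- 1.9106332  # tetrahedral angle, rad
  if (n > 2L) for (k in 3:n) {
    b1 <- xyz[k - 1L, ] - xyz[k - 2L, ]
    b1 <- b1 / sqrt(sum(b1^2))
    perp <- if (k == 3L) c(0, 1, 0) else {
      p <- xyz[k - 3L, ] - xyz[k - 2L, ]
      p <- p - sum(p * b1) * b1
      -p / sqrt(sum(p^2))
    }
    d <- -cos(ang) * b1 + sin(ang) * perp
    xyz[k, ] <- xyz[k - 1L, ] + 1.54 * d
  }
  mol_system(
    data.frame(element = element, name = paste0(element, seq_len(n)),
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               charge = charges, class = "ligand"),
    data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L))
}

# minimal tripeptide-like receptor written as a PDB file; returns the path
write_tripeptide_pdb <- function(path, with_element = TRUE, extra = character()) {
  fmt <- function(serial, name, resn, chain, resno, x, y, z, el, het = FALSE) {
    sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            if (het) "HETATM" else "ATOM", serial,
            if (nchar(name) < 4) paste0(" ", name) else name,
            resn, chain, resno, x, y, z, if (with_element) el else "")
  }
  lines <- c(
    fmt(1, "N",  "ASP", "A", 1, 0.0, 0.0, 0.0, "N"),
    fmt(2, "CA", "ASP", "A", 1, 1.46, 0.0, 0.0, "C"),
    fmt(3, "C",  "ASP", "A", 1, 2.0, 1.4, 0.0, "C"),
    fmt(4, "CB", "ASP", "A", 1, 2.0, -1.2, 0.8, "C"),
    fmt(5, "N",  "GLY", "A", 2, 1.6, 2.6, 0.0, "N"),
    fmt(6, "CA", "GLY", "A", 2, 2.3, 3.9, 0.0, "C"),
    fmt(7, "C",  "GLY", "A", 2, 3.8, 3.8, 0.2, "C"),
    fmt(8, "N",  "LYS", "A", 3, 4.5, 4.9, 0.3, "N"),
    fmt(9, "CA", "LYS", "A", 3, 6.0, 4.9, 0.4, "C"),
    fmt(10, "C", "LYS", "A", 3, 6.6, 6.3, 0.4, "C"),
    fmt(11, "NZ", "LYS", "A", 3, 6.7, 4.1, 1.6, "N"),
    fmt(12, "O", "HOH", "A", 90, 3.0, 0.5, 2.0, "O", het = TRUE),
    extra,
    "END")
  writeLines(lines, path)
  path
}

# SDF text for a 3-atom charged fragment; state id in the title line
sdf_record <- function(state_id, shift = 0) {
  c(state_id, "  fixture", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0 + shift, 0, 0, "N"),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            1.47 + shift, 0, 0, "C"),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            2.1 + shift, 1.3, 0, "O"),
    "  1  2  1  0", "  2  3  1  0",
    "M  CHG  2   1   1   3  -1",
    "M  END", "$$$$")
}

write_fixture_sdf <- function(path, ids = c("S1", "S2", "S3")) {
  writeLines(unlist(lapply(seq_along(ids),
                           function(k) sdf_record(ids[k], shift = (k - 1) * 5))),
             path)
  path
}

write_fixture_manifest <- function(path, ids = c("S1", "S2", "S3"),
                                   parents = ids,
                                   labels = rep("ligand", length(ids))) {
  writeLines(c("state_id\tparent_id\tlabel",
               paste(ids, parents, labels, sep = "\t")), path)
  path
}

# brute-force minimum heavy-atom distance between a residue and pose atoms
brute_residue_selection <- function(receptor, poses, cutoff) {
  a <- receptor$atoms
  pose_xyz <- do.call(rbind, lapply(poses, function(p) {
    s <- if (inherits(p, "docked_pose")) p$system else p
    as.matrix(s$atoms[s$atoms$heavy, c("x", "y", "z"), drop = FALSE])
  }))
  keys <- unique(paste(a$chain, a$resid, sep = "|")[a$class == "protein"])
  keep <- vapply(keys, function(key) {
    rows <- a$class == "protein" & paste(a$chain, a$resid, sep = "|") == key &
      a$heavy
    rx <- as.matrix(a[rows, c("x", "y", "z"), drop = FALSE])
    best <- Inf
    for (i in seq_len(nrow(rx))) {
      for (j in seq_len(nrow(pose_xyz))) {
        best <- min(best, sqrt(sum((rx[i, ] - pose_xyz[j, ])^2)))
      }
    }
    best <= cutoff
  }, TRUE)
  keys[keep]
}

# brute-force enrichment factor by direct counting
brute_ef <- function(scores, labels, x) {
  ord <- order(scores)
  n <- length(scores)
  n_x <- ceiling(x * n / 100)
  hits_x <- sum(labels[ord][seq_len(n_x)])
  (hits_x / n_x) / (sum(labels) / n)
}

# brute-force AUC by Mann-Whitney pair counting (lower score = better)
brute_auc <- function(scores, labels) {
  lig <- scores[labels]; dec <- scores[!labels]
  tot <- 0
  for (l in lig) tot <- tot + sum(l < dec) + 0.5 * sum(l == dec)
  tot / (length(lig) * length(dec))
}
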