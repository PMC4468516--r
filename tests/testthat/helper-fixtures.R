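# Shared builders and independent oracles for the test suite. Fixtures are
# constructed in code; no binary files.

# minimal sm_structure from parallel vectors
build_structure <- function(id, resid, elety, elesy, resno, xyz,
                            chain = "A", type = "ATOM") {
  n <- length(resno)
  atoms <- data.frame(type = rep(type, length.out = n),
                      elety = rep(elety, length.out = n),
                      elesy = rep(elesy, length.out = n),
                      resid = rep(resid, length.out = n),
                      chain = rep(chain, length.out = n),
                      resno = resno, icode = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
                      stringsAsFactors = FALSE)
  atoms$res <- paste0(atoms$chain, ":", atoms$resno)
  structure(list(id = id, atoms = atoms, source = NA_character_),
            class = "sm_structure")
}

make_site <- function(structure, residues = NULL) {
  res <- if (is.null(residues))
    unique(structure$atoms$res[structure$atoms$type == "ATOM"]) else residues
  structure(list(protein_id = structure$id, residues = res,
                 ref_ligand_id = "REF", radius = 10), class = "sm_site")
}

# minimal sm_pose
make_pose <- function(id, elesy, xyz, bonds = NULL, charge = 0L,
                      energy = NA_real_, protein_id = NA_character_) {
  n <- length(elesy)
  atoms <- data.frame(elesy = elesy, charge = rep(charge, length.out = n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (is.null(bonds))
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  heavy <- atoms$elesy != "H"
  structure(list(compound_id = id, protein_id = protein_id, atoms = atoms,
                 bonds = bonds, energy = energy, M = sum(heavy)),
            class = "sm_pose")
}

# a tiny hand-written PDB: 3 residues on chain A (one with insertion code and
# an altloc pair), 1 residue on chain B, plus a 2-atom HETATM ligand
tiny_pdb_text <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   GLY A   1       2.100   1.100   0.000  1.00  0.00           O",
    "ATOM      4  CA ASER A   2       4.000   0.000   0.000  0.40  0.00           C",
    "ATOM      5  CA BSER A   2       4.050   0.000   0.000  0.60  0.00           C",
    "ATOM      6  OG  SER A   2       5.000   1.000   0.000  1.00  0.00           O",
    "ATOM      7  CA  ALA A   2A      8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      8  CA  LYS B   1       0.000   8.000   0.000  1.00  0.00           C",
    "ATOM      9  NZ  LYS B   1       1.000   9.000   0.000  1.00  0.00           N",
    "HETATM   10  C1  LIG A 901       2.000   0.500   2.500  1.00  0.00           C",
    "HETATM   11  O1  LIG A 901       3.000   0.500   3.200  1.00  0.00           O",
    "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_text(), path)
  path
}

# independent superposition oracle: quaternion eigendecomposition (Horn 1987)
quaternion_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- sweep(X, 2, cx); B <- sweep(Y, 2, cy)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- sweep(sweep(X, 2, cx) %*% t(R), 2, cy, "+")
  sqrt(mean(rowSums((fitted - Y)^2)))
}

rotation_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ct * diag(3) + st * rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]),
                            c(-u[2], u[1], 0)) + (1 - ct) * (u %o% u)
}

# independent scalar PLP evaluation (own piecewise arithmetic)
plp_scalar <- function(d, knots, well, clash) {
  if (d < knots[1]) return(clash * (knots[1] - d) / knots[1])
  if (d < knots[2]) return(well * (d - knots[1]) / (knots[2] - knots[1]))
  if (d <= knots[3]) return(well)
  if (d < knots[4]) return(well * (knots[4] - d) / (knots[4] - knots[3]))
  0
}

# exhaustive all-pairs interaction energy oracle: explicit loops over every
# (ligand heavy atom, site heavy atom) pair, classifying each pair and adding
# its scalar PLP energy
brute_pose_energy <- function(pose, structure, site, params = default_plp_params()) {
  a <- structure$atoms
  sa <- a[a$type == "ATOM" & a$res %in% site$residues & a$elesy != "H", , drop = FALSE]
  proles <- sitemoiety:::protein_atom_roles(sa$resid, sa$elety, sa$elesy)
  lig <- pose$atoms
  lroles <- type_atoms(pose)
  total <- 0
  for (i in seq_len(nrow(lig))) {
    if (lig$elesy[i] == "H") next
    for (j in seq_len(nrow(sa))) {
      d <- sqrt((lig$x[i] - sa$x[j])^2 + (lig$y[i] - sa$y[j])^2 +
                (lig$z[i] - sa$z[j])^2)
      lq <- sign(lig$charge[i]); pq <- if (proles[j] == "positive") 1
        else if (proles[j] == "negative") -1 else 0
      lr <- lroles[i]; pr <- proles[j]
      dcap <- function(r) r %in% c("donor", "both", "positive")
      acap <- function(r) r %in% c("acceptor", "both", "negative")
      cls <- if (lq * pq < 0) "elec"
             else if ((dcap(lr) && acap(pr)) || (acap(lr) && dcap(pr))) "hbond"
             else "steric"
      p <- params[[cls]]
      if (d < p$knots[4]) total <- total + plp_scalar(d, p$knots, p$well, p$clash)
    }
  }
  total
}

# per-residue brute-force summed steric energy (for V-event checks)
brute_residue_steric <- function(pose, structure, site, res,
                                 params = default_plp_params()) {
  a <- structure$atoms
  sa <- a[a$type == "ATOM" & a$res == res & a$elesy != "H", , drop = FALSE]
  proles <- sitemoiety:::protein_atom_roles(sa$resid, sa$elety, sa$elesy)
  lig <- pose$atoms
  lroles <- type_atoms(pose)
  total <- 0
  for (i in seq_len(nrow(lig))) {
    if (lig$elesy[i] == "H") next
    for (j in seq_len(nrow(sa))) {
      lq <- sign(lig$charge[i]); pq <- if (proles[j] == "positive") 1
        else if (proles[j] == "negative") -1 else 0
      dcap <- function(r) r %in% c("donor", "both", "positive")
      acap <- function(r) r %in% c("acceptor", "both", "negative")
      lr <- lroles[i]; pr <- proles[j]
      is_steric <- !(lq * pq < 0) &&
        !((dcap(lr) && acap(pr)) || (acap(lr) && dcap(pr)))
      if (!is_steric) next
      d <- sqrt((lig$x[i] - sa$x[j])^2 + (lig$y[i] - sa$y[j])^2 +
                (lig$z[i] - sa$z[j])^2)
      p <- params$steric
      if (d < p$knots[4]) total <- total + plp_scalar(d, p$knots, p$well, p$clash)
    }
  }
  total
}

# synthetic sm_map with hand-placed anchors (for alignment/labeling tests)
synthetic_map <- function(protein_id, centers, types,
                          residues = NULL) {
  anchors <- lapply(seq_len(nrow(centers)), function(i) {
    res <- if (is.null(residues)) paste0("A:", i) else residues[[i]]
    structure(list(id = paste0(types[i], i), protein_id = protein_id,
                   type = types[i], center = as.numeric(centers[i, ]),
                   residues = data.frame(res = res, z = 5, n_events = 50,
                                         stringsAsFactors = FALSE),
                   n_events = 50, event_idx = integer(0), moieties = NULL),
              class = "sm_anchor")
  })
  structure(list(protein_id = protein_id, anchors = anchors,
                 site = structure(list(protein_id = protein_id,
                                       residues = paste0("A:", 1:20),
                                       ref_ligand_id = "REF", radius = 10),
                                  class = "sm_site"),
                 ztables = NULL, events = NULL, compounds = character(0),
                 provenance = NULL),
            class = "sm_map")
}

# small benzene-ring molecule with substituents, kekulized (orders 1/2)
ring_molecule <- function(oh_positions = 1L, cooh = FALSE, id = "ring") {
  theta <- seq(0, by = pi / 3, length.out = 6)
  ring_xyz <- cbind(1.4 * cos(theta), 1.4 * sin(theta), 0)
  elesy <- rep("C", 6)
  bonds <- data.frame(from = 1:6, to = c(2:6, 1), order = rep(c(2L, 1L), 3))
  xyz <- ring_xyz
  charge <- rep(0L, 6)
  for (p in oh_positions) {
    xyz <- rbind(xyz, ring_xyz[p, ] * 1.9)
    elesy <- c(elesy, "O"); charge <- c(charge, 0L)
    bonds <- rbind(bonds, data.frame(from = p, to = length(elesy), order = 1L))
  }
  if (cooh) {
    cpos <- nrow(xyz) + 1L
    xyz <- rbind(xyz, ring_xyz[4, ] * 1.9, ring_xyz[4, ] * 2.4 + c(0, 0.8, 0),
                 ring_xyz[4, ] * 2.4 - c(0, 0.8, 0))
    elesy <- c(elesy, "C", "O", "O"); charge <- c(charge, 0L, 0L, 0L)
    bonds <- rbind(bonds,
                   data.frame(from = c(4L, cpos, cpos),
                              to = c(cpos, cpos + 1L, cpos + 2L),
                              order = c(1L, 2L, 1L)))
  }
  make_pose(id, elesy, xyz, bonds, charge = charge)
}

# build one protein map + structure from the generator (shared by screen tests)
fixture_map <- function(fx, k = 1, seed = 7, config = sm_config()) {
  suppressMessages(build_site_moiety_map(
    fx$structures[[k]], fx$poses[[k]], site = fx$sites[[k]],
    seed = seed, config = config))
}
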