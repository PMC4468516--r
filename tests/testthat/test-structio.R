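test_that("PDB reading keeps numbering, chains, insertion codes and best altloc", {
  path <- write_tiny_pdb()
  st <- read_structure(path, id = "tiny")
  prot <- st$atoms[st$atoms$type == "ATOM", ]
  expect_setequal(unique(prot$res), c("A:1", "A:2", "A:2A", "B:1"))
  # altloc: only the 0.60-occupancy SER CA survives
  ser_ca <- prot[prot$res == "A:2" & prot$elety == "CA", ]
  expect_equal(nrow(ser_ca), 1L)
  expect_equal(ser_ca$x, 4.05)
  # HETATM ligand retained
  expect_true(any(st$atoms$type == "HETATM" & st$atoms$resid == "LIG"))
})

test_that("structures round-trip through PDB at format precision", {
  path <- write_tiny_pdb()
  st <- read_structure(path)
  out <- tempfile(fileext = ".pdb")
  write_structure(st, out)
  st2 <- read_structure(out)
  expect_equal(st2$atoms$res, st$atoms$res)
  expect_equal(st2$atoms$x, st$atoms$x, tolerance = 1e-3)
  expect_equal(st2$atoms$y, st$atoms$y, tolerance = 1e-3)
  expect_equal(st2$atoms$z, st$atoms$z, tolerance = 1e-3)
})

test_that("a HETATM-only file is rejected", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  LIG A 901       0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_error(read_structure(path), "no protein residues")
})

test_that("binding-site inclusion is a closed 10 A ball around heavy atoms", {
  # three single-atom residues at 5.0, 10.0 and 10.1 A from a one-atom ligand
  st <- build_structure("p", resid = "NPL", elety = "CA", elesy = "C",
                        resno = 1:3,
                        xyz = rbind(c(5, 0, 0), c(10, 0, 0), c(10.1, 0, 0)))
  lig <- make_pose("REF", "C", rbind(c(0, 0, 0)))
  site <- define_binding_site(st, lig, radius = 10)
  expect_identical(site$residues, c("A:1", "A:2"))
  expect_error(define_binding_site(st, lig, radius = 0.5), "empty binding site")
})

test_that("binding sites grow monotonically with radius", {
  set.seed(41)
  st <- build_structure("p", "NPL", "CA", "C", resno = 1:30,
                        xyz = matrix(runif(90, -15, 15), 30))
  lig <- make_pose("REF", "C", rbind(c(0, 0, 0), c(2, 0, 0)))
  radii <- c(4, 7, 10, 14)
  sites <- lapply(radii, function(r)
    tryCatch(define_binding_site(st, lig, r)$residues, error = function(e) character(0)))
  for (i in seq_len(length(radii) - 1))
    expect_true(all(sites[[i]] %in% sites[[i + 1]]))
})

test_that("the generator's pocket is exactly recovered by site definition", {
  fx <- make_group1_kinase("group1", seed = 3, n_compounds = 5)
  site <- define_binding_site(fx$structures[[1]], fx$ref_ligand, radius = 10)
  expect_setequal(site$residues, fx$sites[[1]]$residues)
  expect_length(site$residues, 15L)
})

test_that("superposition is exact for identity and known rotations", {
  set.seed(11)
  xyz <- matrix(rnorm(30, sd = 5), 10)
  st <- build_structure("a", "GLY", "CA", "C", resno = 1:10, xyz = xyz)
  pairs <- data.frame(m = paste0("A:", 1:10), r = paste0("A:", 1:10))
  fit0 <- superimpose(st, st, pairs)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  R <- rotation_about(c(1, 2, 3), 0.7)
  moved <- st
  m <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  moved$atoms$x <- m[, 1] + 4; moved$atoms$y <- m[, 2] - 2; moved$atoms$z <- m[, 3] + 1
  fit <- superimpose(moved, st, pairs)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, t(R), tolerance = 1e-8)  # inverse of the applied rotation
  expect_equal(as.matrix(fit$structure$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("superposition RMSD agrees with the quaternion oracle on noisy clouds", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(rnorm(30, sd = 4), 10)
    R <- rotation_about(rnorm(3), runif(1, 0, pi))
    Y <- X %*% t(R) + matrix(rnorm(30, sd = 0.1), 10)
    stX <- build_structure("x", "GLY", "CA", "C", 1:10, X)
    stY <- build_structure("y", "GLY", "CA", "C", 1:10, Y)
    pairs <- data.frame(m = paste0("A:", 1:10), r = paste0("A:", 1:10))
    fit <- superimpose(stX, stY, pairs)
    expect_equal(fit$rmsd, quaternion_fit(X, Y), tolerance = 1e-6)
  }
})

test_that("superposition RMSD is invariant under a common rigid transform", {
  set.seed(13)
  X <- matrix(rnorm(24, sd = 4), 8)
  Y <- X + matrix(rnorm(24, sd = 0.3), 8)
  pairs <- data.frame(m = paste0("A:", 1:8), r = paste0("A:", 1:8))
  base <- superimpose(build_structure("x", "GLY", "CA", "C", 1:8, X),
                      build_structure("y", "GLY", "CA", "C", 1:8, Y), pairs)$rmsd
  R <- rotation_about(c(0, 0, 1), 1.1)
  shift <- c(3, -7, 2)
  Xr <- sweep(X %*% t(R), 2, shift, "+"); Yr <- sweep(Y %*% t(R), 2, shift, "+")
  moved <- superimpose(build_structure("x", "GLY", "CA", "C", 1:8, Xr),
                       build_structure("y", "GLY", "CA", "C", 1:8, Yr), pairs)$rmsd
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("underdetermined superpositions are rejected", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  st <- build_structure("lin", "GLY", "CA", "C", 1:4, xyz)
  pairs2 <- data.frame(m = paste0("A:", 1:2), r = paste0("A:", 1:2))
  expect_error(superimpose(st, st, pairs2), "underdetermined")
  pairs4 <- data.frame(m = paste0("A:", 1:4), r = paste0("A:", 1:4))
  expect_error(superimpose(st, st, pairs4), "collinear")
})

test_that("SDF poses round-trip with charges, energies and heavy-atom counts", {
  # ethanol: C-C-O plus two explicit hydrogens -> M = 3
  eth <- make_pose("ethanol", c("C", "C", "O", "H", "H"),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0),
                         c(-0.5, 0.9, 0), c(-0.5, -0.9, 0)),
                   bonds = data.frame(from = c(1, 2, 1, 1), to = c(2, 3, 4, 5),
                                      order = 1L),
                   energy = -70.0)
  charged <- make_pose("amine", c("N", "C"), rbind(c(0, 0, 1), c(1.4, 0, 1)),
                       bonds = data.frame(from = 1L, to = 2L, order = 1L),
                       charge = c(1L, 0L))
  path <- tempfile(fileext = ".sdf")
  write_poses(list(eth, charged), path)
  back <- read_poses(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$M, 3L)
  expect_equal(back[[1]]$energy, -70.0)
  expect_equal(back[[2]]$atoms$charge, c(1L, 0L))
  expect_true(is.na(back[[2]]$energy))
  expect_equal(back[[1]]$atoms$x, eth$atoms$x, tolerance = 1e-4)
})

test_that("records without 3D coordinates are skipped with a warning", {
  flat <- make_pose("flat", c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)),
                    bonds = data.frame(from = 1L, to = 2L, order = 1L))
  good <- make_pose("good", c("C", "O"), rbind(c(0, 0, 1), c(1.4, 0, 1)),
                    bonds = data.frame(from = 1L, to = 2L, order = 1L))
  path <- tempfile(fileext = ".sdf")
  write_poses(list(flat, good), path)
  expect_warning(back <- read_poses(path), "3D")
  expect_length(back, 1L)
  expect_equal(back[[1]]$compound_id, "good")
})

test_that("multi-record MOL2 files are read with integerized charges", {
  path <- tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "mol_one", " 3 2 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 C1          0.0000    0.0000   20.0000 C.3     1  LIG1        0.0000",
    "      2 C2          1.2000    0.0000   20.0000 C.3     1  LIG1        0.0000",
    "      3 O1          2.4000    0.5000   20.0000 O.3     1  LIG1       -0.0500",
    "@<TRIPOS>BOND", "     1    1    2 1", "     2    2    3 1",
    "@<TRIPOS>MOLECULE", "mol_two", " 2 1 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 N1          0.0000    1.0000   20.0000 N.4     1  LIG2        1.0000",
    "      2 C1          1.2000    1.0000   20.0000 C.3     1  LIG2        0.0000",
    "@<TRIPOS>BOND", "     1    1    2 1"), path)
  poses <- read_poses(path)
  expect_length(poses, 2L)
  expect_equal(poses[[1]]$compound_id, "mol_one")
  expect_equal(poses[[1]]$M, 3L)
  expect_equal(poses[[2]]$atoms$charge[1], 1L)
})
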