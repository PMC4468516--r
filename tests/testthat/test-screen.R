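anchor_at <- function(center, type, res) structure(
  list(id = paste0(type, "1"), protein_id = "p", type = type,
       center = center,
       residues = data.frame(res = res, z = 10, n_events = 50,
                             stringsAsFactors = FALSE),
       n_events = 50L, event_idx = integer(0), moieties = NULL),
  class = "sm_anchor")

test_that("anchor matching needs proximity and the right interaction type", {
  st <- build_structure("p", "ACC", "O1", "O", resno = 1, xyz = rbind(c(0, 0, 0)))
  site <- make_site(st)
  anchor <- anchor_at(c(1.45, 0, 0), "H", "A:1")
  hyd <- make_pose("m", c("C", "O"), rbind(c(4.3, 0, 0), c(2.9, 0, 0)),
                   bonds = data.frame(from = 1L, to = 2L, order = 1L))
  ev <- call_interactions(hyd, st, site)
  expect_equal(match_anchor(hyd, anchor, ev), 1L)
  # same geometry, wrong anchor type (no electrostatic event exists here)
  elec_anchor <- anchor_at(c(1.45, 0, 0), "E", "A:1")
  expect_equal(match_anchor(hyd, elec_anchor, ev), 0L)
  # no heavy atom within the match radius
  far_anchor <- anchor_at(c(20, 0, 0), "H", "A:1")
  expect_equal(match_anchor(hyd, far_anchor, ev), 0L)
})

test_that("the total score combines matches, energies and size as specified", {
  expect_equal(total_score(rep(1L, 7), E = -70, M = 25), -28)
  expect_equal(total_score(rep(0L, 7), E = -70, M = 25), -14)
  # strictly improving in each added match when E < 0
  scores <- vapply(0:7, function(k)
    total_score(c(rep(1L, k), rep(0L, 7 - k)), E = -70, M = 25), numeric(1))
  expect_true(all(diff(scores) < 0))
  # strictly worsening in M for fixed matches
  ms <- vapply(c(10, 20, 40, 80), function(m)
    total_score(rep(1L, 7), E = -70, M = m), numeric(1))
  expect_true(all(diff(ms) > 0))
  # multi-protein averaging
  expect_equal(total_score(list(rep(1L, 4), rep(0L, 2)), E = c(-40, -60), M = 16),
               ((-40 * 2) + (-60 * 1)) / 2 / 4)
  expect_error(total_score(rep(1L, 3), E = -10, M = 0), "M")
})

test_that("moiety energies are consistent with pose energies and the PLP", {
  st <- build_structure("p", "ACC", "O1", "O", resno = 1:2,
                        xyz = rbind(c(0, 0, 0), c(10, 0, 0)))
  site <- make_site(st)
  pose <- make_pose("m", c("C", "O"), rbind(c(30, 0, 0), c(2.9, 0, 0)),
                    bonds = data.frame(from = 1L, to = 2L, order = 1L))
  # moiety beyond range of all residues
  expect_equal(moiety_energy(pose, 1L, st, site$residues), 0)
  # single flat-bottom H-bond contact scores the well depth
  expect_equal(moiety_energy(pose, 2L, st, site$residues), -2.5)
  # whole pose against whole site equals pose_energy
  expect_equal(moiety_energy(pose, 1:2, st, site$residues),
               pose_energy(pose, st, site))
  expect_error(moiety_energy(pose, integer(0), st, site$residues), "empty moiety")
})

test_that("mutation deltas are zero/positive/antisymmetric as expected", {
  wt <- build_structure("wt", "NPL", "CA", "C", resno = 1:2,
                        xyz = rbind(c(0, 0, 0), c(10, 0, 0)))
  site <- make_site(wt)
  pose <- make_pose("m", "C", rbind(c(4.0, 0, 0)))
  expect_equal(mutation_delta(pose, wt, wt, site), 0)
  # mutant grows a clashing side-chain atom 1 A from the ligand atom
  mut <- wt
  mut$atoms <- rbind(mut$atoms,
                     within(mut$atoms[1, ], { elety <- "CB"; x <- 3.0 }))
  expect_gt(mutation_delta(pose, wt, mut, site), 0)
  expect_equal(mutation_delta(pose, wt, mut, site),
               -mutation_delta(pose, mut, wt, site))
  # mutation farther than the potential range barely moves the energy
  mut_far <- wt
  mut_far$atoms <- rbind(mut_far$atoms,
                         within(mut_far$atoms[2, ], { elety <- "CB"; x <- 14 }))
  expect_lt(abs(mutation_delta(pose, wt, mut_far, site)), 0.5)
  # residue-set mismatches are reported
  mut_miss <- wt
  mut_miss$atoms <- mut_miss$atoms[1, , drop = FALSE]
  expect_warning(mutation_delta(pose, wt, mut_miss, site), "A:2")
})

test_that("library ranking bins by specific matches before sorting by score", {
  # 3-protein panel; all carry CH cluster, p1/p2 carry CHG
  sts <- lapply(1:3, function(k)
    build_structure(paste0("p", k), c("ACC", "NPL"), c("O1", "CA"), c("O", "C"),
                    resno = 1:2, xyz = rbind(c(0, 0, 0), c(10, 0, 0))))
  names(sts) <- paste0("p", 1:3)
  mk_map <- function(pid, with_chg) {
    anchors <- list(anchor_at(c(1.45, 0, 0), "H", "A:1"))
    if (with_chg) anchors <- c(anchors, list(anchor_at(c(11.9, 0, 0), "V", "A:2")))
    structure(list(protein_id = pid, anchors = anchors,
                   site = make_site(sts[[pid]]), ztables = NULL, events = NULL,
                   compounds = character(0), provenance = NULL),
              class = "sm_map")
  }
  maps <- list(p1 = mk_map("p1", TRUE), p2 = mk_map("p2", TRUE),
               p3 = mk_map("p3", FALSE))
  clusters <- list(
    structure(list(id = "cluster01", type = "H", center = c(1.45, 0, 0),
                   members = c(p1 = "H1", p2 = "H1", p3 = "H1"), n_members = 3L,
                   label = "specific", presence = 1, region = "CH"),
              class = "sm_cluster"),
    structure(list(id = "cluster02", type = "V", center = c(11.9, 0, 0),
                   members = c(p1 = "V1", p2 = "V1"), n_members = 2L,
                   label = "specific", presence = 2 / 3, region = "CHG"),
              class = "sm_cluster"))
  # compound "dual" hydrogen-bonds A:1 and grazes A:2; "chonly" only the former;
  # "plain" touches neither anchor
  dual <- make_pose("dual", c("C", "O", "C"),
                    rbind(c(6, 3, 0), c(2.9, 0, 0), c(13.0, 0, 2.0)),
                    bonds = data.frame(from = c(1, 1), to = c(2, 3), order = 1L),
                    energy = -50)
  chonly <- make_pose("chonly", c("C", "O"), rbind(c(6, 3, 0), c(2.9, 0, 0)),
                      bonds = data.frame(from = 1L, to = 2L, order = 1L),
                      energy = -30)
  plain <- make_pose("plain", "C", rbind(c(5, 5, 5)), energy = -90)
  pose_sets <- lapply(sts, function(s) list(dual = dual, chonly = chonly,
                                            plain = plain))
  rk <- rank_library(pose_sets, maps, sts, clusters)
  expect_setequal(rk$bin, c("Group 1", "Group 2", "Group 3"))
  expect_equal(rk$compound_id[rk$bin == "Group 1"], "dual")
  expect_equal(rk$compound_id[rk$bin == "Group 2"], "chonly")
  expect_equal(rk$compound_id[rk$bin == "Group 3"], "plain")
  # bins partition the library
  expect_equal(sort(rk$compound_id), sort(c("dual", "chonly", "plain")))
  expect_false(anyDuplicated(rk$compound_id) > 0)
  # compounds missing a pose somewhere are dropped with a warning
  pose_sets$p3$dual <- NULL
  expect_warning(rk2 <- rank_library(pose_sets, maps, sts, clusters), "missing")
  expect_false("dual" %in% rk2$compound_id)
})

test_that("rigid motion of pose and map together preserves anchor matches", {
  st <- build_structure("p", "ACC", "O1", "O", resno = 1, xyz = rbind(c(0, 0, 0)))
  site <- make_site(st)
  anchor <- anchor_at(c(1.45, 0, 0), "H", "A:1")
  pose <- make_pose("m", c("C", "O"), rbind(c(4.3, 0, 0), c(2.9, 0, 0)),
                    bonds = data.frame(from = 1L, to = 2L, order = 1L))
  base <- match_anchor(pose, anchor, call_interactions(pose, st, site))
  R <- rotation_about(c(1, 1, 0), 0.9); shift <- c(5, -3, 2)
  mv <- function(xyz) sweep(xyz %*% t(R), 2, shift, "+")
  st2 <- st; m <- mv(as.matrix(st$atoms[, c("x", "y", "z")]))
  st2$atoms$x <- m[, 1]; st2$atoms$y <- m[, 2]; st2$atoms$z <- m[, 3]
  pose2 <- pose; m2 <- mv(as.matrix(pose$atoms[, c("x", "y", "z")]))
  pose2$atoms$x <- m2[, 1]; pose2$atoms$y <- m2[, 2]; pose2$atoms$z <- m2[, 3]
  anchor2 <- anchor; anchor2$center <- as.numeric(mv(rbind(anchor$center)))
  moved <- match_anchor(pose2, anchor2, call_interactions(pose2, st2, site))
  expect_equal(moved, base)
  expect_equal(base, 1L)
})

test_that("compound clustering picks one representative per scaffold", {
  ring1 <- ring_molecule(oh_positions = 1L, id = "b_phenol")
  ring1b <- ring_molecule(oh_positions = 1L, id = "a_phenol")   # duplicate scaffold
  chain <- make_pose("chain", c("C", "C", "C", "C", "N"),
                     rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4.5, 0, 0),
                           c(6, 0, 0)),
                     bonds = data.frame(from = 1:4, to = 2:5, order = 1L))
  path <- tempfile(fileext = ".sdf")
  write_poses(list(ring1, ring1b, chain), path)
  cl <- cluster_compounds(path, cutoff = 0.4)
  expect_equal(length(unique(cl$cluster)), 2L)
  dup <- cl[cl$compound_id %in% c("a_phenol", "b_phenol"), ]
  expect_equal(length(unique(dup$cluster)), 1L)
  expect_equal(dup$representative, dup$compound_id == "a_phenol")
  expect_equal(sum(cl$representative), 2L)
})

test_that("compound clustering agrees with a brute-force average-linkage oracle", {
  set.seed(27)
  mols <- lapply(1:10, function(i) {
    n <- sample(4:8, 1)
    el <- sample(c("C", "N", "O"), n, replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))
    make_pose(sprintf("m%02d", i), el,
              cbind(seq_len(n) * 1.5, rep(0, n), rep(0, n)),
              bonds = data.frame(from = seq_len(n - 1), to = seq_len(n - 1) + 1L,
                                 order = 1L))
  })
  path <- tempfile(fileext = ".sdf")
  write_poses(mols, path)
  sdf <- ChemmineR::read.SDFset(path)
  ap <- ChemmineR::sdf2ap(sdf)
  n <- length(mols)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- 1 - ChemmineR::cmp.similarity(ap[i], ap[j])
  }
  # naive agglomerative average linkage written out longhand
  groups <- as.list(seq_len(n))
  repeat {
    best <- NULL; bd <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (b <= a) next
      d <- mean(D[groups[[a]], groups[[b]]])
      if (d < bd) { bd <- d; best <- c(a, b) }
    }
    if (is.null(best) || bd > 0.5) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  oracle <- integer(n)
  for (g in seq_along(groups)) oracle[groups[[g]]] <- g
  got <- cluster_compounds(path, cutoff = 0.5)
  # same partition up to label renaming
  expect_equal(length(unique(got$cluster)), length(groups))
  tab <- table(oracle, got$cluster[match(sprintf("m%02d", 1:10), got$compound_id)])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})
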