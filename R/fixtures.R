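# Synthetic pocket / pose-ensemble generator with planted interaction
# hotspots. The generator emulates the statistical structure the anchor
# pipeline assumes: a panel of superimposed pockets in one frame, consensus
# contacts at hotspot residues (high contact probability), sparse background
# contacts elsewhere, and subset-specific hotspots shared by only part of the
# panel.
#
# Geometry: 15 single-atom pseudo-residues on a jittered subset of a 3 x 3 x 3
# grid with 10 A spacing (any two residues, and in particular any two
# hotspots, are at least 10 A apart -- far beyond twice the 3.5 A anchor
# linkage cutoff). Contact atoms are placed on a random direction from their
# target residue at the class's attractive distance; with 10 A spacing every
# such placement is already at or beyond the steric outer knot (6 A) from
# every other residue, so planted atoms contribute exactly zero energy to
# residues other than their target, no spurious interaction can be called,
# and event midpoints are unbiased estimates of the hotspot position (a
# residual clearance check guards the jittered worst case). Ligand scaffolds
# sit ~20 A above the pocket.
#
# The pocket composition keeps the permutation null honest: for every
# interaction type and every hotspot-subset variant, the planted hotspot mass
# (contacts at probability 0.8) dominates the row totals, so the shuffled
# expectation per column stays above the 0.05 background rate and background
# residues are depleted relative to the null, as the method assumes of real
# non-hotspot residues.

# hotspot slots: 5 core (PA/IA/RB/AP/BP-like) + CH-like + CHG-like. The
# adenine-ring slots split into a hydrogen-bonding (PA) and a van der Waals
# (IA) hotspot; ribose-like RB is van der Waals, the phosphate-like AP/BP are
# electrostatic; the C-terminal-hinge-like CH is hydrogen-bonding and the
# hinge/G-loop-like CHG van der Waals.
hotspot_layout <- function() {
  data.frame(
    name = c("PA", "IA", "RB", "AP", "BP", "CH", "CHG"),
    type = c("H", "V", "V", "E", "E", "H", "V"),
    x = c(0, 10, 0, -10, 0, 0, 10),
    y = c(0, 0, 10, 0, -10, 0, 10),
    z = c(0, 0, 0, 0, 0, 10, 0),
    stringsAsFactors = FALSE)
}

# background residues: two of each hydrogen-bonding flavor, one of each
# charge, two nonpolar -- grid slots disjoint from the hotspot slots
background_layout <- function() {
  data.frame(
    role = c("NPL", "NPL", "ACC", "ACC", "DON", "DAC", "NEG", "POS"),
    x = c(10, -10, 0, 10, -10, 0, 0, -10),
    y = c(-10, 10, 0, 0, 0, 10, -10, -10),
    z = c(0, 0, -10, 10, 10, 10, 10, 0),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic fixture panel
#'
#' Defines the study conditions of the generator: panel size, planted
#' hotspots, contact probabilities and noise. The defaults are the package's
#' reference conditions: 200 compounds, hotspot contact probability 0.8,
#' background contact probability 0.05, 0.1 A positional noise, a panel of 10
#' pockets in which all carry the five core-region hotspots, 7 carry the
#' CH-like hotspot and 4 carry both CH- and CHG-like hotspots.
#'
#' @param seed integer seed; recorded in all outputs.
#' @param panel_size number of pocket structures.
#' @param n_compounds compounds per pocket (P).
#' @param contact_prob per-compound contact probability at a hotspot residue.
#' @param background_prob contact probability at background residues.
#' @param noise_sd Gaussian positional noise on contact atoms, Angstrom.
#' @param hotspots data frame (`name`, `type` in H/E/V, `x`, `y`, `z`) of
#'   planted hotspots; defaults to the 7-slot core + CH + CHG layout.
#' @param background data frame (`role` in NPL/ACC/DON/DAC/NEG/POS, `x`, `y`,
#'   `z`) of background residues; defaults to the shipped 8-residue layout.
#' @param specific named list: hotspot name -> integer vector of panel member
#'   indices carrying it; hotspots not listed are present in every pocket.
#'   `NULL` (the default) places the CH-like hotspot in the first 70% and the
#'   CHG-like hotspot in the first 40% of the panel (rounded), i.e. 7 and 4
#'   pockets at the default panel size.
#' @param poses_per_compound docked poses generated per compound (the best is
#'   used downstream).
#' @return An `sm_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 7L, panel_size = 10L, n_compounds = 200L,
                         contact_prob = 0.8, background_prob = 0.05,
                         noise_sd = 0.1, hotspots = hotspot_layout(),
                         background = background_layout(),
                         specific = NULL,
                         poses_per_compound = 1L) {
  if (is.null(specific))
    specific <- list(CH = seq_len(round(0.7 * panel_size)),
                     CHG = seq_len(round(0.4 * panel_size)))
  stopifnot(contact_prob >= 0, contact_prob <= 1,
            background_prob >= 0, background_prob <= 1,
            panel_size >= 1, n_compounds >= 1, noise_sd >= 0)
  if (nrow(hotspots)) {
    hx <- as.matrix(hotspots[, c("x", "y", "z")])
    if (nrow(hx) > 1) {
      dmin <- min(stats::dist(hx))
      if (dmin < 2 * 3.5)
        stop("inseparable hotspots: minimum pairwise distance ", round(dmin, 2),
             " A is below twice the anchor linkage cutoff")
    }
    if (!all(hotspots$type %in% c("H", "E", "V")))
      stop("hotspot types must be H, E or V")
  }
  if (!all(background$role %in% names(elem_of_role)))
    stop("unknown background residue role")
  all_pos <- rbind(as.matrix(hotspots[, c("x", "y", "z")]),
                   as.matrix(background[, c("x", "y", "z")]))
  if (nrow(all_pos) > 1 && min(stats::dist(all_pos)) < 2 * 3.5)
    stop("pocket residues closer than twice the anchor linkage cutoff")
  specific <- specific[names(specific) %in% hotspots$name]
  for (nm in names(specific))
    if (any(specific[[nm]] < 1 | specific[[nm]] > panel_size))
      stop("specific subset for ", nm, " outside the panel")
  structure(list(seed = as.integer(seed), panel_size = as.integer(panel_size),
                 n_compounds = as.integer(n_compounds),
                 contact_prob = contact_prob, background_prob = background_prob,
                 noise_sd = noise_sd, hotspots = hotspots,
                 background = background, specific = specific,
                 poses_per_compound = as.integer(poses_per_compound)),
            class = "sm_fixture_spec")
}

# residue template for a role / contact type
role_of_type <- c(H = "ACC", E = "NEG", V = "NPL")     # residue side
elem_of_role <- c(ACC = "O", DON = "N", DAC = "O", NEG = "O",
                  POS = "N", NPL = "C")
# ligand contact atom complementary to a residue role, with the distance band
# of the resulting pair class (inside the attractive flat bottom of the PLP)
lig_atom_for <- function(role) {
  switch(role,
         ACC = , DON = , DAC = list(elesy = "O", charge = 0L, dmin = 2.7, dmax = 2.9),
         NEG = list(elesy = "N", charge = 1L, dmin = 2.6, dmax = 3.0),
         POS = list(elesy = "O", charge = -1L, dmin = 2.6, dmax = 3.0),
         NPL = list(elesy = "C", charge = 0L, dmin = 3.6, dmax = 4.0))
}

#' Generate a synthetic pocket panel with planted hotspots
#'
#' Builds `panel_size` single-atom-residue pocket structures in one shared
#' frame, a docked pose ensemble per pocket whose contacts are sampled from
#' the spec's probabilities and realized inside the attractive bands of the
#' default piecewise linear potential, plus the ground truth: planted anchors,
#' per-pocket specific-hotspot presence and the implied group of each pocket.
#'
#' @param spec an [fixture_spec()].
#' @return An `sm_fixture`: list with `structures` (list of `sm_structure`),
#'   `poses` (list over proteins of named `sm_pose` lists), `sites` (list of
#'   `sm_site`), `ref_ligand`, `truth` (list: `hotspots` data frame with the
#'   ideal grid positions/types/residues, `positions` data frame with the
#'   realized per-protein hotspot coordinates, `presence` logical matrix
#'   protein x hotspot, `groups` data frame), and `spec`.
#' @export
make_panel <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "sm_fixture_spec"))
  restore <- set_local_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  hs <- spec$hotspots
  # pocket = hotspot slots + background slots, ordered by position for neutral
  # residue numbering
  pocket <- rbind(
    data.frame(role = unname(role_of_type[hs$type]),
               x = hs$x, y = hs$y, z = hs$z, stringsAsFactors = FALSE),
    spec$background[, c("role", "x", "y", "z")])
  ord <- order(pocket$z, pocket$y, pocket$x)
  pocket <- pocket[ord, , drop = FALSE]
  hs_idx <- match(seq_len(nrow(hs)), ord)   # residue index of each hotspot
  grid <- as.matrix(pocket[, c("x", "y", "z")])
  n_res <- nrow(grid)
  bg_roles <- pocket$role

  structures <- vector("list", spec$panel_size)
  pose_sets <- vector("list", spec$panel_size)
  sites <- vector("list", spec$panel_size)
  presence <- matrix(TRUE, spec$panel_size, nrow(hs),
                     dimnames = list(NULL, hs$name))
  for (nm in names(spec$specific))
    presence[, nm] <- seq_len(spec$panel_size) %in% spec$specific[[nm]]

  realized <- list()   # per-protein realized hotspot coordinates
  for (k in seq_len(spec$panel_size)) {
    pid <- sprintf("prot%02d", k)
    roles <- bg_roles
    if (nrow(hs)) roles[hs_idx] <- role_of_type[hs$type]  # hotspot-compatible roles
    rpos <- grid + matrix(stats::rnorm(n_res * 3, 0, 0.3), n_res, 3)
    if (nrow(hs))
      realized[[k]] <- data.frame(protein = pid, name = hs$name, type = hs$type,
                                  x = rpos[hs_idx, 1], y = rpos[hs_idx, 2],
                                  z = rpos[hs_idx, 3],
                                  present = presence[k, , drop = TRUE],
                                  stringsAsFactors = FALSE)
    atoms <- data.frame(
      type = "ATOM", elety = "CA",
      elesy = unname(elem_of_role[roles]),
      resid = roles, chain = "A", resno = seq_len(n_res), icode = "",
      x = rpos[, 1], y = rpos[, 2], z = rpos[, 3], o = 1,
      stringsAsFactors = FALSE)
    atoms$res <- residue_id(atoms$chain, atoms$resno, atoms$icode)
    structures[[k]] <- structure(list(id = pid, atoms = atoms, source = NA_character_),
                                 class = "sm_structure")
    sites[[k]] <- structure(list(protein_id = pid, residues = atoms$res,
                                 ref_ligand_id = "REF", radius = 10),
                            class = "sm_site")

    active_hs <- which(presence[k, , drop = TRUE])
    poses <- vector("list", spec$n_compounds)
    for (p in seq_len(spec$n_compounds)) {
      cid <- sprintf("cmp%04d", p)
      best <- NULL
      for (rep_i in seq_len(spec$poses_per_compound)) {
        pose <- sample_pose(cid, pid, rpos, roles, hs, active_hs, hs_idx, spec)
        if (is.null(best) || pose$energy < best$energy) best <- pose
      }
      poses[[p]] <- best
    }
    names(poses) <- vapply(poses, function(p) p$compound_id, character(1))
    pose_sets[[k]] <- poses
  }
  names(structures) <- names(pose_sets) <- names(sites) <-
    vapply(structures, function(s) s$id, character(1))

  ref_atoms <- expand.grid(x = c(-5, 5), y = c(-5, 5), z = c(-5, 5))
  ref_ligand <- new_pose("REF", NA_character_,
                         atoms = data.frame(elesy = "C", charge = 0L,
                                            x = ref_atoms$x, y = ref_atoms$y,
                                            z = ref_atoms$z,
                                            stringsAsFactors = FALSE),
                         bonds = data.frame(from = integer(0), to = integer(0),
                                            order = integer(0)))

  truth_hs <- if (nrow(hs)) cbind(hs, residue = residue_id("A", hs_idx, ""))
              else cbind(hs, residue = character(0))
  spec_names <- names(spec$specific)
  groups <- data.frame(protein = names(structures), stringsAsFactors = FALSE)
  groups$specific <- apply(presence[, spec_names, drop = FALSE], 1, function(r)
    paste(sort(spec_names[r]), collapse = ","))
  if (setequal(spec_names, c("CH", "CHG"))) {
    groups$group <- ifelse(groups$specific == "CH,CHG", "Group 1",
                    ifelse(groups$specific == "CH", "Group 2", "Group 3"))
  } else {
    groups$group <- ifelse(groups$specific == "", "none", groups$specific)
  }
  structure(list(structures = structures, poses = pose_sets, sites = sites,
                 ref_ligand = ref_ligand,
                 truth = list(hotspots = truth_hs, presence = presence,
                              positions = if (length(realized))
                                do.call(rbind, realized) else NULL,
                              groups = groups),
                 spec = spec),
            class = "sm_fixture")
}

# sample one docked pose: Bernoulli contacts at active hotspots and (type-
# compatible) background residues, contact atoms placed in the attractive
# band of their class, rejection-sampled to stay > 6.2 A from other residues
sample_pose <- function(cid, pid, rpos, roles, hs, active_hs, hs_idx, spec) {
  n_res <- nrow(rpos)
  contacts <- list()
  bg_type <- c(ACC = "H", DON = "H", DAC = "H", NEG = "E", POS = "E", NPL = "V")
  for (i in active_hs) {
    if (stats::runif(1) < spec$contact_prob)
      contacts[[length(contacts) + 1L]] <- list(res = hs_idx[i], type = hs$type[i])
  }
  bg <- setdiff(seq_len(n_res), hs_idx)
  hit <- bg[stats::runif(length(bg)) < spec$background_prob]
  for (r in hit)
    contacts[[length(contacts) + 1L]] <- list(res = r, type = unname(bg_type[roles[r]]))

  n_scaffold <- 3L
  sx <- cbind(stats::runif(1, -4, 4) + 1.5 * (seq_len(n_scaffold) - 2),
              stats::runif(1, -4, 4) + numeric(n_scaffold),
              20 + stats::rnorm(n_scaffold, 0, 0.5))
  atoms <- data.frame(elesy = rep("C", n_scaffold), charge = 0L,
                      x = sx[, 1], y = sx[, 2], z = sx[, 3],
                      stringsAsFactors = FALSE)
  bonds <- data.frame(from = seq_len(n_scaffold - 1), to = seq_len(n_scaffold - 1) + 1L,
                      order = 1L)
  e_plant <- 0
  well <- c(H = -2.5, E = -4.0, V = -0.4)
  for (ct in contacts) {
    la <- lig_atom_for(roles[ct$res])
    target <- rpos[ct$res, ]
    others <- rpos[-ct$res, , drop = FALSE]
    pos <- NULL
    for (try in 1:60) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d <- stats::runif(1, la$dmin, la$dmax)
      cand <- target + d * u + stats::rnorm(3, 0, spec$noise_sd)
      if (min(sqrt(rowSums(sweep(others, 2, cand)^2))) >= 6.0) { pos <- cand; break }
    }
    if (is.null(pos)) next
    atoms <- rbind(atoms, data.frame(elesy = la$elesy, charge = la$charge,
                                     x = pos[1], y = pos[2], z = pos[3],
                                     stringsAsFactors = FALSE))
    bonds <- rbind(bonds, data.frame(from = 1L, to = nrow(atoms), order = 1L))
    e_plant <- e_plant + well[[ct$type]]
  }
  new_pose(cid, pid, atoms, bonds,
           energy = e_plant + stats::runif(1, -1, 0))
}

#' Single-pocket fixtures emulating the anchor-class presets
#'
#' `preset = "group1"` plants all 7 hotspots (5 core-region + CH-like +
#' CHG-like), `"ch_only"` drops the CHG-like hotspot (6), `"core_only"` keeps
#' only the 5 core-region hotspots.
#'
#' @param preset one of `"group1"`, `"ch_only"`, `"core_only"`.
#' @param seed integer seed.
#' @param n_compounds compounds in the ensemble.
#' @param ... further overrides passed to [fixture_spec()].
#' @return An `sm_fixture` with a single structure/pose set.
#' @export
make_group1_kinase <- function(preset = c("group1", "ch_only", "core_only"),
                               seed = 7L, n_compounds = 200L, ...) {
  preset <- match.arg(preset)
  hs <- hotspot_layout()
  hs <- switch(preset,
               group1 = hs,
               ch_only = hs[hs$name != "CHG", , drop = FALSE],
               core_only = hs[!hs$name %in% c("CH", "CHG"), , drop = FALSE])
  spec <- fixture_spec(seed = seed, panel_size = 1L, n_compounds = n_compounds,
                       hotspots = hs, specific = list(), ...)
  make_panel(spec)
}

#' Write a fixture to disk (PDB structures, SDF poses, ground-truth JSON)
#'
#' @param fixture an `sm_fixture`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- fixture$ref_ligand$atoms
  ref_rows <- data.frame(type = "HETATM",
                         elety = paste0("C", seq_len(nrow(ref))),
                         elesy = ref$elesy, resid = "REF", chain = "L",
                         resno = 900L, icode = "",
                         x = ref$x, y = ref$y, z = ref$z, o = 1,
                         stringsAsFactors = FALSE)
  ref_rows$res <- residue_id(ref_rows$chain, ref_rows$resno, ref_rows$icode)
  for (pid in names(fixture$structures)) {
    st <- fixture$structures[[pid]]
    st$atoms <- rbind(st$atoms, ref_rows)   # embed the reference ligand
    write_structure(st, file.path(dir, paste0(pid, ".pdb")))
    write_poses(fixture$poses[[pid]], file.path(dir, paste0(pid, "_poses.sdf")))
  }
  truth <- fixture$truth
  jsonlite::write_json(
    list(schema = "sitemoiety/fixture-truth/v1",
         seed = fixture$spec$seed,
         hotspots = truth$hotspots,
         presence = as.data.frame(truth$presence),
         groups = truth$groups),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Name aligned clusters after the planted hotspots they recover
#'
#' Matches each aligned anchor cluster to the nearest planted hotspot of the
#' same interaction type within `max_dist` of its center, returning a named
#' vector suitable for `label_clusters(region_names = )`. Clusters recovering
#' no planted hotspot are omitted.
#'
#' @param clusters list of `sm_cluster` from [align_maps()]/[label_clusters()].
#' @param fixture the `sm_fixture` the panel came from.
#' @param max_dist maximum center-to-hotspot distance, Angstrom.
#' @return Named character vector: cluster id -> hotspot name.
#' @export
assign_truth_regions <- function(clusters, fixture, max_dist = 2.0) {
  hs <- fixture$truth$hotspots
  out <- character(0)
  for (cl in clusters) {
    same <- hs[hs$type == cl$type, , drop = FALSE]
    if (nrow(same) == 0) next
    d <- sqrt((same$x - cl$center[1])^2 + (same$y - cl$center[2])^2 +
              (same$z - cl$center[3])^2)
    if (min(d) <= max_dist) out[cl$id] <- same$name[which.min(d)]
  }
  out
}
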