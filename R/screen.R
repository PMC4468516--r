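#' Does a pose match an anchor?
#'
#' A compound matches an anchor when (i) some ligand heavy atom lies within
#' `match_radius` of the anchor center and (ii) an event of the anchor's
#' interaction type links the pose to at least one anchor member residue. In
#' strict mode the contributing atom of such an event must additionally
#' belong to one of the anchor's preferred functional groups.
#'
#' @param pose an `sm_pose` docked into the anchor's protein.
#' @param anchor an `sm_anchor`.
#' @param events event data frame for this pose against the anchor's protein.
#' @param match_radius Angstrom.
#' @param strict require a preferred moiety (default FALSE).
#' @return 0 or 1.
#' @export
match_anchor <- function(pose, anchor, events, match_radius = 3.0, strict = FALSE) {
  xyz <- pose_xyz(pose)
  d2 <- (xyz[, 1] - anchor$center[1])^2 + (xyz[, 2] - anchor$center[2])^2 +
        (xyz[, 3] - anchor$center[3])^2
  if (!any(d2 <= match_radius^2)) return(0L)
  ev <- events[events$compound_id == pose$compound_id &
               events$type == anchor$type &
               events$res %in% anchor$residues$res, , drop = FALSE]
  if (nrow(ev) == 0) return(0L)
  if (strict && !is.null(anchor$moieties) && nrow(anchor$moieties)) {
    preferred <- setdiff(anchor$moieties$group, "other")
    g <- pose_graph(pose)
    ok <- vapply(ev$lig_atom, function(ai)
      classify_moiety(pose, ai, g) %in% preferred, logical(1))
    if (!any(ok)) return(0L)
  }
  1L
}

#' Total site-moiety-map score
#'
#' Combines anchor matches and docked energies over the K panel proteins:
#' `TS = (1/K) * sum_k [ E_k * (1 + sum_a AS_ka / A_k) ] / sqrt(M)`,
#' where `AS_ka` is the binary anchor match of the compound in anchor a of
#' protein k, `A_k` the anchor count of protein k, `E_k` the docked energy
#' (kcal/mol, negative favorable) and `M` the compound's heavy-atom count.
#' The square root of M tempers the advantage of high-molecular-weight
#' compounds. Lower (more negative) scores are better.
#'
#' @param AS list (length K) of binary match vectors, one per protein (or a
#'   single vector when K = 1).
#' @param E numeric vector of docked energies, length K.
#' @param M heavy-atom count, >= 1.
#' @return The total score (dimensionless).
#' @export
total_score <- function(AS, E, M) {
  if (!is.list(AS)) AS <- list(AS)
  K <- length(AS)
  if (length(E) != K) stop("need one energy per protein")
  if (!is.numeric(M) || M < 1) stop("M must be >= 1")
  per_k <- vapply(seq_len(K), function(k) {
    A <- length(AS[[k]])
    frac <- if (A > 0) sum(AS[[k]]) / A else 0
    E[k] * (1 + frac)
  }, numeric(1))
  mean(per_k) / sqrt(M)
}

#' Rank a screening library against a protein panel
#'
#' For each compound with a pose in every panel protein: computes its events,
#' per-protein anchor-match vector, docked energy (pose-file property when
#' present, else [pose_energy()]) and total score; then bins compounds by
#' their specific-anchor match pattern (a specific cluster counts as matched
#' when the compound matches its member anchor in at least
#' `specific_match_fraction` of the proteins carrying it) and sorts by total
#' score within bins. Compounds missing a pose in some protein are excluded
#' with a warning.
#'
#' @param pose_sets named list (protein id -> named list of `sm_pose` by
#'   compound id).
#' @param maps named list of `sm_map` for the panel proteins.
#' @param structures named list of `sm_structure` (same frame as the poses).
#' @param clusters labeled aligned clusters ([label_clusters()]) giving the
#'   specific anchors; may be NULL for a single-protein screen (no binning).
#' @param config an [sm_config()].
#' @param params a `plp_params` table.
#' @return Data frame (class `sm_ranking`): `compound_id`, `bin`, `matched`
#'   (comma-joined specific regions), `TS`, `M`, one `E_<protein>` and
#'   `AS_<protein>` column per panel protein, `rank` (within bin).
#' @export
rank_library <- function(pose_sets, maps, structures, clusters = NULL,
                         config = sm_config(), params = default_plp_params()) {
  panel <- names(maps)
  stopifnot(!is.null(panel), all(panel %in% names(pose_sets)),
            all(panel %in% names(structures)))
  all_cmp <- sort(unique(unlist(lapply(pose_sets[panel], names))))
  keep <- vapply(all_cmp, function(cid)
    all(vapply(panel, function(p) cid %in% names(pose_sets[[p]]), logical(1))),
    logical(1))
  if (any(!keep))
    warning(sum(!keep), " compound(s) missing a pose in some panel protein; excluded")
  cmps <- all_cmp[keep]
  if (length(cmps) == 0) stop("no compound has poses in every panel protein")
  spec <- if (is.null(clusters)) list() else
    Filter(function(cl) identical(cl$label, "specific"), clusters)
  spec_name <- vapply(spec, function(cl)
    if (!is.na(cl$region)) cl$region else cl$id, character(1))

  rows <- vector("list", length(cmps))
  for (ci in seq_along(cmps)) {
    cid <- cmps[ci]
    AS <- list(); E <- numeric(0)
    matched_anchor <- list()  # protein -> anchor ids matched
    M <- NA_integer_
    for (p in panel) {
      pose <- pose_sets[[p]][[cid]]
      m <- maps[[p]]
      ev <- call_interactions(pose, structures[[p]], m$site, params,
                              vdw_threshold = config$vdw_threshold)
      as_vec <- vapply(m$anchors, function(a)
        match_anchor(pose, a, ev, config$match_radius, config$strict_moiety),
        integer(1))
      names(as_vec) <- vapply(m$anchors, function(a) a$id, character(1))
      AS[[p]] <- as_vec
      E[p] <- if (!is.na(pose$energy)) pose$energy else
        pose_energy(pose, structures[[p]], m$site, params)
      matched_anchor[[p]] <- names(as_vec)[as_vec == 1L]
      M <- pose$M
    }
    ts <- total_score(AS, unname(E), M)
    # specific-anchor pattern across the panel
    spec_hit <- character(0)
    for (si in seq_along(spec)) {
      cl <- spec[[si]]
      carriers <- intersect(names(cl$members), panel)
      if (length(carriers) == 0) next
      hits <- vapply(carriers, function(p)
        cl$members[[p]] %in% matched_anchor[[p]], logical(1))
      if (mean(hits) >= config$specific_match_fraction)
        spec_hit <- c(spec_hit, spec_name[si])
    }
    row <- data.frame(compound_id = cid,
                      matched = paste(sort(spec_hit), collapse = ","),
                      TS = ts, M = M, stringsAsFactors = FALSE)
    for (p in panel) {
      row[[paste0("E_", p)]] <- unname(E[p])
      row[[paste0("AS_", p)]] <- paste(AS[[p]], collapse = "")
    }
    rows[[ci]] <- row
  }
  out <- do.call(rbind, rows)
  if (length(spec) && all(c("CH", "CHG") %in% spec_name)) {
    out$bin <- ifelse(out$matched == "CH,CHG", "Group 1",
               ifelse(out$matched == "CH", "Group 2",
               ifelse(out$matched == "", "Group 3", out$matched)))
  } else {
    out$bin <- ifelse(out$matched == "", "core only", out$matched)
  }
  out <- out[order(out$bin, out$TS, out$compound_id), , drop = FALSE]
  out$rank <- stats::ave(out$TS, out$bin, FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("sm_ranking", "data.frame")
  out
}

#' Interaction energy of a designated moiety against a residue subset
#'
#' Sums the class-wise piecewise-linear-potential pair energies between the
#' given ligand atoms and all heavy atoms of the given residues only, e.g. a
#' substituent's interaction energy with the member residues of an anchor.
#'
#' @param pose an `sm_pose`.
#' @param moiety_atoms integer indices into `pose$atoms` designating the
#'   moiety (must be non-empty).
#' @param structure an `sm_structure`.
#' @param residues character vector of residue ids.
#' @param params a `plp_params` table.
#' @return Energy in kcal/mol.
#' @export
moiety_energy <- function(pose, moiety_atoms, structure, residues,
                          params = default_plp_params()) {
  if (length(moiety_atoms) == 0) stop("empty moiety")
  sub_site <- structure(list(protein_id = structure$id, residues = residues,
                             ref_ligand_id = NA_character_, radius = NA_real_),
                        class = "sm_site")
  # roles come from the full molecular graph; only the moiety atoms are scored
  roles_full <- type_atoms(pose)
  satoms <- site_atoms(structure, sub_site)
  a <- pose$atoms[moiety_atoms, , drop = FALSE]
  heavy <- a$elesy != "H"
  lx <- as.matrix(a[heavy, c("x", "y", "z")])
  if (nrow(lx) == 0) stop("moiety has no heavy atoms")
  px <- as.matrix(satoms[, c("x", "y", "z")])
  D <- sqrt(pmax(outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * lx %*% t(px), 0))
  cls <- pair_class_matrix(roles_full[moiety_atoms][heavy], satoms$role)
  total <- 0
  for (cl in c("steric", "hbond", "elec")) {
    m <- cls == cl & D < params[[cl]]$knots[4]
    if (any(m)) total <- total + sum(plp_energy(D[m], params[[cl]]))
  }
  total
}

#' Docked-energy difference between wild-type and mutant structures
#'
#' `delta = pose_energy(mutant) - pose_energy(wild-type)` for the same pose in
#' the same frame; positive values mean the mutation costs favorable
#' interactions or introduces clashes. Residues outside the mutated positions
#' are expected to correspond; mismatches are reported with a warning.
#'
#' @param pose an `sm_pose`.
#' @param wt_structure,mut_structure superimposed `sm_structure` objects.
#' @param site an `sm_site` (in wild-type residue ids; the same ids are used
#'   in the mutant).
#' @param params a `plp_params` table.
#' @return Energy difference in kcal/mol.
#' @export
mutation_delta <- function(pose, wt_structure, mut_structure, site,
                           params = default_plp_params()) {
  wt_res <- unique(wt_structure$atoms$res[wt_structure$atoms$type == "ATOM"])
  mut_res <- unique(mut_structure$atoms$res[mut_structure$atoms$type == "ATOM"])
  only <- union(setdiff(wt_res, mut_res), setdiff(mut_res, wt_res))
  if (length(only))
    warning("residues present in only one structure: ",
            paste(only, collapse = ", "))
  e_wt <- pose_energy(pose, wt_structure, site, params)
  mut_site <- site
  mut_site$residues <- intersect(site$residues, mut_res)
  e_mut <- pose_energy(pose, mut_structure, mut_site, params)
  e_mut - e_wt
}

#' Cluster a compound library and pick representatives
#'
#' Atom-pair topological descriptors (ChemmineR) give pairwise Tanimoto
#' similarities; compounds are average-linkage clustered on 1 - Tanimoto and
#' cut at `cutoff` (or into `k` clusters); the representative of each cluster
#' is its lexicographically smallest compound id.
#'
#' @param sdf an `SDFset` (ChemmineR) or path to an SDF file.
#' @param cutoff distance (1 - Tanimoto) cut height.
#' @param k alternatively, number of clusters.
#' @return Data frame: `compound_id`, `cluster`, `representative` (logical).
#' @export
cluster_compounds <- function(sdf, cutoff = NULL, k = NULL) {
  if (is.character(sdf)) sdf <- ChemmineR::read.SDFset(sdf, skipErrors = TRUE)
  ok <- ChemmineR::validSDF(sdf)
  if (any(!ok)) warning(sum(!ok), " unparseable molecule(s) skipped")
  sdf <- sdf[ok]
  ids <- unname(ChemmineR::sdfid(sdf))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  n <- length(sdf)
  if (n == 0) stop("no valid molecules")
  if (is.null(cutoff) && is.null(k)) stop("supply cutoff or k")
  apset <- ChemmineR::sdf2ap(sdf)
  sim <- matrix(1, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      s <- ChemmineR::cmp.similarity(apset[i], apset[j])
      sim[i, j] <- s; sim[j, i] <- s
    }
  }
  d <- stats::as.dist(1 - sim)
  cl <- if (n == 1) 1L else {
    hc <- stats::hclust(d, method = "average")
    if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = cutoff)
  }
  rep_flag <- logical(n)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    rep_flag[idx[order(ids[idx])][1]] <- TRUE
  }
  data.frame(compound_id = ids, cluster = as.integer(cl),
             representative = rep_flag, stringsAsFactors = FALSE)
}

#' Write a screening ranking as TSV
#'
#' @param ranking an `sm_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
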