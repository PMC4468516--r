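#' Cluster consensus interactions into spatial anchors
#'
#' Pools the midpoints of all events belonging to consensus (residue, type)
#' pairs, separately per interaction type, and single-linkage clusters them at
#' `linkage_cutoff`. Each cluster supported by at least
#' `min_support * n_compounds` events becomes an anchor; its center is the
#' centroid of its event midpoints and its member residues are the consensus
#' residues contributing at least `member_fraction` of their events to the
#' cluster.
#'
#' @param events event data frame over all profiled poses.
#' @param ztables list of `sm_ztable` (one per interaction type, as from
#'   [zscore_profile()]).
#' @param n_compounds number of profiled compounds (support denominator).
#' @param protein_id protein the anchors belong to.
#' @param linkage_cutoff single-linkage distance cutoff, Angstrom.
#' @param min_support minimum supporting-event fraction.
#' @param member_fraction minimum per-residue event fraction for membership.
#' @return List of `sm_anchor` objects: each has `id`, `protein_id`, `type`,
#'   `center` (xyz), `residues` (data frame `res`, `z`, `n_events`),
#'   `n_events`, `event_idx` (row indices into `events`), `moieties` (NULL
#'   until [moiety_preferences()] is applied).
#' @export
cluster_anchors <- function(events, ztables, n_compounds, protein_id = NA_character_,
                            linkage_cutoff = 3.5, min_support = 0.05,
                            member_fraction = 0.25) {
  anchors <- list()
  min_events <- max(1, ceiling(min_support * n_compounds))
  for (zt in ztables) {
    cons <- zt$res[zt$consensus]
    if (length(cons) == 0) next
    ty <- zt$type[1]
    idx <- which(events$type == ty & events$res %in% cons)
    if (length(idx) == 0) next
    pts <- as.matrix(events[idx, c("mx", "my", "mz")])
    cl <- if (length(idx) == 1) 1L else
      stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                    h = linkage_cutoff)
    for (ci in unique(cl)) {
      members <- idx[cl == ci]
      if (length(members) < min_events) next
      center <- colMeans(events[members, c("mx", "my", "mz"), drop = FALSE])
      # residues whose consensus events concentrate in this cluster
      rs <- character(0); rz <- numeric(0); rn <- integer(0)
      for (r in cons) {
        r_all <- sum(events$type == ty & events$res == r)
        r_here <- sum(events$res[members] == r)
        if (r_all > 0 && r_here / r_all >= member_fraction) {
          rs <- c(rs, r)
          rz <- c(rz, zt$z[zt$res == r])
          rn <- c(rn, r_here)
        }
      }
      if (length(rs) == 0) next
      anchors[[length(anchors) + 1L]] <- structure(
        list(id = NA_character_, protein_id = protein_id, type = ty,
             center = as.numeric(center),
             residues = data.frame(res = rs, z = rz, n_events = rn,
                                   stringsAsFactors = FALSE),
             n_events = length(members), event_idx = members, moieties = NULL),
        class = "sm_anchor")
    }
  }
  # deterministic ids: type + rank of center coordinates
  if (length(anchors)) {
    ord <- order(vapply(anchors, function(a) a$type, character(1)),
                 vapply(anchors, function(a) a$center[1], numeric(1)),
                 vapply(anchors, function(a) a$center[2], numeric(1)),
                 vapply(anchors, function(a) a$center[3], numeric(1)))
    anchors <- anchors[ord]
    for (i in seq_along(anchors))
      anchors[[i]]$id <- sprintf("%s%d", anchors[[i]]$type,
                                 sum(vapply(anchors[seq_len(i)], function(a)
                                   a$type == anchors[[i]]$type, logical(1))))
  }
  anchors
}

#' Attach moiety preferences to an anchor
#'
#' Classifies the contributing ligand atom of every supporting event with the
#' shipped functional-group table and reports, per group, the fraction of
#' supporting events and the mean pair energy, sorted by ascending mean energy
#' (most favorable first).
#'
#' @param anchor an `sm_anchor` from [cluster_anchors()].
#' @param events the event data frame the anchor's `event_idx` refers to.
#' @param poses named list of `sm_pose` (names = compound ids) providing the
#'   molecular graphs.
#' @return The anchor with a `moieties` data frame (`group`, `fraction`,
#'   `mean_energy`, `n`).
#' @export
moiety_preferences <- function(anchor, events, poses) {
  if (is.null(names(poses)))
    names(poses) <- vapply(poses, function(p) p$compound_id, character(1))
  ev <- events[anchor$event_idx, , drop = FALSE]
  graphs <- list()
  groups <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    cid <- ev$compound_id[i]
    p <- poses[[cid]]
    if (is.null(p)) { groups[i] <- "other"; next }
    if (is.null(graphs[[cid]])) graphs[[cid]] <- pose_graph(p)
    groups[i] <- classify_moiety(p, ev$lig_atom[i], graphs[[cid]])
  }
  agg <- split(ev$energy, groups)
  tab <- data.frame(group = names(agg),
                    fraction = vapply(agg, length, integer(1)) / nrow(ev),
                    mean_energy = vapply(agg, mean, numeric(1)),
                    n = vapply(agg, length, integer(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$mean_energy), , drop = FALSE]
  rownames(tab) <- NULL
  anchor$moieties <- tab
  anchor
}

#' Build the site-moiety map of one protein
#'
#' Runs the per-protein pipeline: select the top-energy compounds, call typed
#' interactions for every pose, build the three binary interaction profiles,
#' compute permutation Z-scores, cluster consensus interactions into anchors
#' and attach moiety preferences.
#'
#' @param structure an `sm_structure`, superimposed into the panel frame.
#' @param poses list of `sm_pose` docked into `structure` (energies are
#'   computed with [pose_energy()] when missing).
#' @param site an `sm_site`; alternatively pass `ref_ligand` to define it.
#' @param seed random seed for the permutation null (required).
#' @param config an [sm_config()] list.
#' @param params a `plp_params` table.
#' @param ref_ligand optional `sm_pose` used with `config$site_radius` when
#'   `site` is NULL.
#' @return An `sm_map`: list with `protein_id`, `anchors`, `site`, `ztables`,
#'   `events`, `compounds`, `provenance`.
#' @export
build_site_moiety_map <- function(structure, poses, site = NULL, seed,
                                  config = sm_config(),
                                  params = default_plp_params(),
                                  ref_ligand = NULL) {
  if (missing(seed)) stop("build_site_moiety_map requires an explicit seed")
  if (is.null(site)) {
    if (is.null(ref_ligand)) stop("supply either a site or a reference ligand")
    site <- define_binding_site(structure, ref_ligand, config$site_radius)
  }
  en <- vapply(poses, function(p) p$energy, numeric(1))
  if (any(is.na(en))) {
    for (i in which(is.na(en)))
      poses[[i]]$energy <- pose_energy(poses[[i]], structure, site, params)
  }
  top <- select_top_poses(poses, n = config$top_n)
  names(top) <- vapply(top, function(p) p$compound_id, character(1))
  events <- do.call(rbind, lapply(top, call_interactions, structure = structure,
                                  site = site, params = params,
                                  vdw_threshold = config$vdw_threshold))
  rownames(events) <- NULL
  compounds <- names(top)
  profiles <- build_profiles(events, compounds, site)
  ztables <- lapply(profiles, zscore_profile, n_shuffles = config$n_shuffles,
                    seed = seed, confidence = config$confidence)
  anchors <- cluster_anchors(events, ztables, n_compounds = length(compounds),
                             protein_id = structure$id,
                             linkage_cutoff = config$linkage_cutoff,
                             min_support = config$min_support,
                             member_fraction = config$member_fraction)
  anchors <- lapply(anchors, moiety_preferences, events = events, poses = top)
  structure(list(protein_id = structure$id, anchors = anchors, site = site,
                 ztables = ztables, events = events, compounds = compounds,
                 provenance = provenance_block(config, seed,
                                               list(n_poses = length(compounds)))),
            class = "sm_map")
}

#' @export
print.sm_map <- function(x, ...) {
  cat("<sm_map>", x$protein_id, "-", length(x$anchors), "anchors (",
      paste(vapply(x$anchors, function(a) a$id, character(1)), collapse = ", "),
      ") from", length(x$compounds), "compounds\n")
  invisible(x)
}

#' Write a site-moiety map to JSON
#'
#' Versioned schema; events are not serialized (they are derivable from the
#' structure and poses), anchors, Z-tables, site and provenance are.
#'
#' @param map an `sm_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simmap <- function(map, path) {
  obj <- list(
    schema = "sitemoiety/map/v1",
    protein_id = map$protein_id,
    site = list(protein_id = map$site$protein_id, residues = map$site$residues,
                ref_ligand_id = map$site$ref_ligand_id, radius = map$site$radius),
    anchors = lapply(map$anchors, function(a)
      list(id = a$id, protein_id = a$protein_id, type = a$type,
           center = a$center, residues = a$residues, n_events = a$n_events,
           moieties = a$moieties)),
    ztables = lapply(map$ztables, function(z) as.data.frame(z)),
    compounds = map$compounds,
    provenance = map$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a site-moiety map from JSON
#'
#' @param path path written by [write_simmap()].
#' @return An `sm_map` (without the `events` table).
#' @export
read_simmap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$schema, "sitemoiety/map/v1"))
    stop("unrecognized map schema in ", path)
  anchors <- lapply(seq_len(length(obj$anchors$id)), function(i) {
    structure(list(id = obj$anchors$id[i],
                   protein_id = obj$anchors$protein_id[i],
                   type = obj$anchors$type[i],
                   center = as.numeric(obj$anchors$center[[i]]),
                   residues = as.data.frame(obj$anchors$residues[[i]]),
                   n_events = obj$anchors$n_events[i],
                   event_idx = NULL,
                   moieties = if (!is.null(obj$anchors$moieties))
                     as.data.frame(obj$anchors$moieties[[i]]) else NULL),
              class = "sm_anchor")
  })
  site <- structure(list(protein_id = obj$site$protein_id,
                         residues = obj$site$residues,
                         ref_ligand_id = obj$site$ref_ligand_id,
                         radius = obj$site$radius), class = "sm_site")
  structure(list(protein_id = obj$protein_id, anchors = anchors, site = site,
                 ztables = obj$ztables, events = NULL,
                 compounds = obj$compounds, provenance = obj$provenance),
            class = "sm_map")
}

#' Export the anchor table of a map as TSV
#'
#' @param map an `sm_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(map, path) {
  rows <- lapply(map$anchors, function(a) data.frame(
    anchor = a$id, protein = a$protein_id, type = a$type,
    x = a$center[1], y = a$center[2], z = a$center[3],
    n_events = a$n_events,
    residues = paste(a$residues$res, collapse = ","),
    top_moiety = if (!is.null(a$moieties) && nrow(a$moieties))
      a$moieties$group[1] else NA_character_,
    stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
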