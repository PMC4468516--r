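#' Align anchors across a panel of site-moiety maps
#'
#' Greedy nearest-pair agglomeration: among all cluster pairs of the same
#' interaction type with no shared protein, repeatedly merge the closest pair
#' whose center distance is below `merge_cutoff`, recomputing the cluster
#' center as the centroid of member anchor centers after each merge. Ties are
#' broken by protein id then anchor id, making the result independent of input
#' order. Each protein contributes at most one anchor per cluster.
#'
#' @param maps list of `sm_map` objects in a common coordinate frame
#'   (structures pre-superimposed).
#' @param merge_cutoff center-distance cutoff in Angstrom (anchors closer than
#'   this align).
#' @return List of `sm_cluster` objects: `id`, `type`, `center`, `members`
#'   (named character vector, protein id -> anchor id), `n_members`. Labels
#'   and presence fractions are added by [label_clusters()].
#' @export
align_maps <- function(maps, merge_cutoff = 2.0) {
  if (length(maps) < 2) stop("panel too small: need at least 2 maps")
  panel <- vapply(maps, function(m) m$protein_id, character(1))
  if (anyDuplicated(panel)) stop("duplicate protein ids in panel")
  nodes <- list()
  for (m in maps) for (a in m$anchors) {
    nodes[[length(nodes) + 1L]] <- list(
      type = a$type, center = a$center,
      members = stats::setNames(a$id, m$protein_id))
  }
  if (length(nodes) == 0) return(list())
  # deterministic starting order
  key <- vapply(nodes, function(n) paste(names(n$members), n$members), character(1))
  nodes <- nodes[order(vapply(nodes, function(n) n$type, character(1)), key)]
  repeat {
    best <- NULL; best_d <- merge_cutoff; best_key <- ""
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        if (j <= i) next
        if (nodes[[i]]$type != nodes[[j]]$type) next
        if (length(intersect(names(nodes[[i]]$members),
                             names(nodes[[j]]$members)))) next
        d <- sqrt(sum((nodes[[i]]$center - nodes[[j]]$center)^2))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best) &&
             paste(key_of(nodes[[i]]), key_of(nodes[[j]])) < best_key)) {
          best <- c(i, j); best_d <- d
          best_key <- paste(key_of(nodes[[i]]), key_of(nodes[[j]]))
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    merged <- nodes[[i]]
    merged$members <- c(merged$members, nodes[[j]]$members)
    ni <- length(nodes[[i]]$members); nj <- length(nodes[[j]]$members)
    merged$center <- (nodes[[i]]$center * ni + nodes[[j]]$center * nj) / (ni + nj)
    nodes[[i]] <- merged
    nodes[[j]] <- NULL
  }
  ord <- order(vapply(nodes, function(n) -length(n$members), numeric(1)),
               vapply(nodes, function(n) n$type, character(1)),
               vapply(nodes, function(n) n$center[1], numeric(1)))
  nodes <- nodes[ord]
  lapply(seq_along(nodes), function(i) {
    n <- nodes[[i]]
    structure(list(id = sprintf("cluster%02d", i), type = n$type,
                   center = n$center, members = n$members,
                   n_members = length(n$members), label = NA_character_,
                   presence = NA_real_, region = NA_character_),
              class = "sm_cluster")
  })
}

key_of <- function(node) paste(names(node$members)[1], node$members[1])

#' Label aligned anchor clusters as core, specific or singleton
#'
#' A cluster is core when its presence fraction (members / panel size) exceeds
#' `core_threshold`; otherwise specific when it has at least `min_specific`
#' members; otherwise singleton.
#'
#' @param clusters list of `sm_cluster` from [align_maps()].
#' @param panel_size number of proteins in the panel.
#' @param core_threshold presence fraction strictly above which a cluster is
#'   core.
#' @param min_specific minimum members for a specific cluster.
#' @param region_names optional named character vector mapping cluster id to a
#'   region label (e.g. `c(cluster06 = "CH", cluster07 = "CHG")`).
#' @return The clusters with `label`, `presence` and (optionally) `region`
#'   filled in.
#' @export
label_clusters <- function(clusters, panel_size, core_threshold = 0.90,
                           min_specific = 2L, region_names = NULL) {
  lapply(clusters, function(cl) {
    cl$presence <- cl$n_members / panel_size
    cl$label <- if (cl$presence > core_threshold) "core"
                else if (cl$n_members >= min_specific) "specific"
                else "singleton"
    if (!is.null(region_names) && cl$id %in% names(region_names))
      cl$region <- unname(region_names[[cl$id]])
    cl
  })
}

#' Classify panel proteins by specific-anchor presence
#'
#' Each protein's group key is the exact set of specific clusters it
#' possesses. Keys are mapped to group names via `name_map`; with the default
#' kinase-style map, proteins holding both named specific anchors (regions
#' `CH` and `CHG`) fall in Group 1, `CH` only in Group 2, and none in Group 3.
#' Unmapped keys are reported verbatim.
#'
#' @param clusters labeled clusters from [label_clusters()].
#' @param panel character vector of all panel protein ids.
#' @param name_map named list: group name -> character vector of specific
#'   cluster ids or region names. `NULL` uses the CH/CHG convention when both
#'   regions are assigned, otherwise keys are reported verbatim.
#' @return Data frame (`sm_groups`): `protein`, `specific` (comma-joined
#'   specific anchors present), `group`.
#' @export
classify_groups <- function(clusters, panel, name_map = NULL) {
  spec <- Filter(function(cl) identical(cl$label, "specific"), clusters)
  spec_name <- vapply(spec, function(cl)
    if (!is.na(cl$region)) cl$region else cl$id, character(1))
  present <- lapply(panel, function(p) {
    has <- vapply(spec, function(cl) p %in% names(cl$members), logical(1))
    sort(spec_name[has])
  })
  keys <- vapply(present, paste, character(1), collapse = ",")
  if (is.null(name_map) && all(c("CH", "CHG") %in% spec_name)) {
    name_map <- list(`Group 1` = c("CH", "CHG"), `Group 2` = "CH",
                     `Group 3` = character(0))
  }
  group_of <- function(key_set) {
    if (!is.null(name_map)) {
      for (nm in names(name_map)) {
        if (setequal(key_set, name_map[[nm]])) return(nm)
      }
    }
    if (length(key_set) == 0) "none" else paste(key_set, collapse = "+")
  }
  out <- data.frame(protein = panel,
                    specific = keys,
                    group = vapply(present, group_of, character(1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sm_groups", "data.frame")
  out
}

#' Per-cluster, per-protein anchor residue report
#'
#' For every aligned cluster, lists each member protein's anchor residues
#' (identities and, when available from the maps, residue names), supporting
#' cross-panel comparison of anchor residue patterns.
#'
#' @param clusters labeled clusters.
#' @param maps the panel maps the clusters were aligned from.
#' @return Data frame: `cluster`, `label`, `region`, `type`, `protein`,
#'   `anchor`, `residues` (comma-joined ids), `residue_names` (comma-joined
#'   residue names).
#' @export
anchor_residue_report <- function(clusters, maps) {
  by_id <- stats::setNames(maps, vapply(maps, function(m) m$protein_id, character(1)))
  rows <- list()
  for (cl in clusters) {
    for (p in names(cl$members)) {
      m <- by_id[[p]]
      aid <- cl$members[[p]]
      anchor <- NULL
      for (a in m$anchors) if (identical(a$id, aid)) anchor <- a
      if (is.null(anchor)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl$id, label = cl$label, region = cl$region, type = cl$type,
        protein = p, anchor = aid,
        residues = paste(anchor$residues$res, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(0), label = character(0),
               region = character(0), type = character(0),
               protein = character(0), anchor = character(0),
               residues = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an aligned panel to JSON / read it back
#'
#' @param clusters labeled clusters from [label_clusters()].
#' @param panel character vector of panel protein ids.
#' @param path output path.
#' @return `path` invisibly (`write_panel`); a list with `clusters` and
#'   `panel` (`read_panel`).
#' @export
write_panel <- function(clusters, panel, path) {
  obj <- list(schema = "sitemoiety/panel/v1", panel = panel,
              clusters = lapply(clusters, function(cl)
                list(id = cl$id, type = cl$type, center = cl$center,
                     members = as.list(cl$members), n_members = cl$n_members,
                     label = cl$label, presence = cl$presence,
                     region = cl$region)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "sitemoiety/panel/v1"))
    stop("unrecognized panel schema in ", path)
  clusters <- lapply(obj$clusters, function(cl) {
    structure(list(id = cl$id, type = cl$type,
                   center = as.numeric(unlist(cl$center)),
                   members = unlist(cl$members),
                   n_members = cl$n_members, label = cl$label,
                   presence = cl$presence,
                   region = if (is.null(cl$region)) NA_character_ else cl$region),
              class = "sm_cluster")
  })
  list(clusters = clusters, panel = unlist(obj$panel))
}
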