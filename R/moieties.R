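# Functional-group (moiety) classification of ligand atoms, in the spirit of
# checkmol's functional-group taxonomy. Implemented as a priority-ordered
# table of connectivity rules over element, formal charge, bond orders and
# aromaticity rather than SMARTS; the subset covers the groups relevant to
# hinge-binding chemistry (hydroxyls, catechols, gallate-like rings,
# carboxylates, amides, esters, amines, ethers, carbonyls, nitriles, rings,
# alkyls, thiols, halogens).

#' Functional-group table
#'
#' The shipped moiety vocabulary, in matching priority order (an atom gets the
#' first group whose rule it satisfies).
#'
#' @return Data frame with columns `group` and `description`.
#' @export
sm_moiety_groups <- function() {
  data.frame(
    group = c("carboxylate", "carboxylic acid", "ester oxygen", "amide oxygen",
              "amide nitrogen", "trihydroxyphenyl", "catechol", "phenol",
              "hydroxyl", "ether", "carbonyl", "nitrile", "ammonium",
              "aromatic nitrogen", "primary amine", "secondary amine",
              "tertiary amine", "thiol", "thioether", "halogen",
              "aromatic carbon", "alkyl", "other"),
    description = c(
      "negatively charged O of a -CO2- group",
      "O of a neutral -COOH (hydroxyl O on a carbonyl carbon)",
      "bridging O bonded to a carbonyl carbon",
      "carbonyl O whose carbon also bears N",
      "N bonded to a carbonyl carbon",
      "aromatic C-OH flanked by two adjacent aromatic C-OH (gallate-like)",
      "aromatic C-OH with one adjacent aromatic C-OH",
      "OH on an aromatic carbon",
      "OH on a saturated carbon",
      "O with two single-bonded heavy neighbors",
      "O double-bonded to carbon (ketone/aldehyde)",
      "N triple-bonded to carbon",
      "positively charged nitrogen",
      "ring nitrogen of an aromatic system",
      "N with one heavy neighbor",
      "N with two heavy neighbors",
      "N with three heavy neighbors",
      "SH sulfur", "S with two heavy neighbors",
      "F, Cl, Br or I",
      "carbon of an aromatic ring",
      "saturated carbon", "unclassified atom"),
    stringsAsFactors = FALSE)
}

# adjacency and bond-order bookkeeping for one pose
pose_graph <- function(pose) {
  n <- nrow(pose$atoms)
  nbr <- vector("list", n)
  ord <- vector("list", n)
  b <- pose$bonds
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      f <- b$from[i]; t <- b$to[i]; o <- b$order[i]
      nbr[[f]] <- c(nbr[[f]], t); ord[[f]] <- c(ord[[f]], o)
      nbr[[t]] <- c(nbr[[t]], f); ord[[t]] <- c(ord[[t]], o)
    }
  }
  list(nbr = nbr, ord = ord, elem = toupper(pose$atoms$elesy),
       charge = pose$atoms$charge, aromatic = aromatic_atoms(pose))
}

# Aromatic atoms: ends of order-4 bonds, plus members of 6-rings of C/N with
# three double bonds (kekulized aromatic rings), found via igraph 6-cycle
# subisomorphisms.
aromatic_atoms <- function(pose) {
  n <- nrow(pose$atoms)
  arom <- logical(n)
  b <- pose$bonds
  if (!nrow(b)) return(arom)
  arom[unique(c(b$from[b$order == 4], b$to[b$order == 4]))] <- TRUE
  heavy_ok <- toupper(pose$atoms$elesy) %in% c("C", "N")
  if (nrow(b) >= 6 && sum(heavy_ok) >= 6) {
    g <- igraph::graph_from_edgelist(cbind(b$from, b$to), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    iso <- tryCatch(
      igraph::subgraph_isomorphisms(igraph::make_ring(6), g, method = "vf2"),
      error = function(e) list())
    seen <- character(0)
    for (mp in iso) {
      ring <- as.integer(mp)
      key <- paste(sort(ring), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (!all(heavy_ok[ring])) next
      # count double bonds along the cycle
      dbl <- 0L
      for (i in seq_len(6)) {
        u <- ring[i]; v <- ring[if (i == 6) 1 else i + 1]
        o <- b$order[(b$from == u & b$to == v) | (b$from == v & b$to == u)]
        if (length(o) && max(o) >= 2) dbl <- dbl + 1L
      }
      if (dbl >= 3) arom[ring] <- TRUE
    }
  }
  arom
}

#' Classify the functional group of a ligand atom
#'
#' Applies the shipped moiety rule table ([sm_moiety_groups()]) to one atom of
#' a pose, using formal charge, bond orders, heavy-atom connectivity and
#' aromaticity.
#'
#' @param pose an `sm_pose`.
#' @param atom atom index (1-based row of `pose$atoms`).
#' @param graph optional precomputed [pose_graph] (internal reuse).
#' @return A group name from [sm_moiety_groups()].
#' @export
classify_moiety <- function(pose, atom, graph = NULL) {
  g <- if (is.null(graph)) pose_graph(pose) else graph
  e <- g$elem[atom]
  nb <- g$nbr[[atom]]; bo <- g$ord[[atom]]
  heavy <- g$elem[nb] != "H"
  nb <- nb[heavy]; bo <- bo[heavy]
  deg <- length(nb)
  ch <- g$charge[atom]
  is_carbonyl_c <- function(ci) {
    cn <- g$nbr[[ci]]; co <- g$ord[[ci]]
    any(g$elem[cn] == "O" & co == 2)
  }
  if (e == "O") {
    cnb <- nb[g$elem[nb] == "C"]
    if (ch < 0) {
      if (length(cnb) && any(vapply(cnb, is_carbonyl_c, logical(1))))
        return("carboxylate")
      return("carboxylate")           # charged O treated as carboxylate-like
    }
    if (deg == 1 && bo[1] >= 2) {     # carbonyl oxygen
      ci <- nb[1]
      cn <- g$nbr[[ci]]
      if (any(g$elem[cn] == "N")) return("amide oxygen")
      return("carbonyl")
    }
    if (deg == 1) {                    # hydroxyl-like
      ci <- nb[1]
      if (g$elem[ci] == "C") {
        if (is_carbonyl_c(ci)) return("carboxylic acid")
        if (g$aromatic[ci]) {
          ring_oh <- aromatic_oh_neighbors(g, ci, atom)
          if (ring_oh >= 2) return("trihydroxyphenyl")
          if (ring_oh == 1) return("catechol")
          return("phenol")
        }
      }
      return("hydroxyl")
    }
    if (deg >= 2) {
      if (any(vapply(nb[g$elem[nb] == "C"], is_carbonyl_c, logical(1))))
        return("ester oxygen")
      return("ether")
    }
    return("other")
  }
  if (e == "N") {
    if (ch > 0) return("ammonium")
    if (length(bo) && any(bo >= 3) && !any(bo == 4)) return("nitrile")
    if (g$aromatic[atom]) return("aromatic nitrogen")
    if (length(nb) && any(vapply(nb[g$elem[nb] == "C"], is_carbonyl_c, logical(1))))
      return("amide nitrogen")
    if (deg <= 1) return("primary amine")
    if (deg == 2) return("secondary amine")
    return("tertiary amine")
  }
  if (e == "S") {
    if (deg <= 1) return("thiol")
    return("thioether")
  }
  if (e %in% c("F", "CL", "BR", "I")) return("halogen")
  if (e == "C") {
    if (g$aromatic[atom]) return("aromatic carbon")
    return("alkyl")
  }
  "other"
}

# number of aromatic neighbors of ring carbon `ci` (excluding the query OH)
# that themselves carry a single-bonded terminal oxygen
aromatic_oh_neighbors <- function(g, ci, oh_atom) {
  ring_nb <- g$nbr[[ci]]
  ring_nb <- ring_nb[g$aromatic[ring_nb] & g$elem[ring_nb] == "C"]
  cnt <- 0L
  for (rc in ring_nb) {
    os <- g$nbr[[rc]]
    oo <- g$ord[[rc]]
    has_oh <- any(g$elem[os] == "O" & oo == 1 & os != oh_atom &
                  vapply(os, function(o) length(g$nbr[[o]][g$elem[g$nbr[[o]]] != "H"]) == 1,
                         logical(1)))
    if (has_oh) cnt <- cnt + 1L
  }
  cnt
}
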