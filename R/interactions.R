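# Atom roles drive contact typing. Roles: donor, acceptor, both (donor and
# acceptor), positive, negative, nonpolar. Charged atoms participate in
# electrostatic pairs with opposite charges and can otherwise act as H-bond
# donors (positive) or acceptors (negative) toward neutral polar partners.

#' Assign hydrogen-bonding/charge roles to ligand atoms
#'
#' Deterministic rules over element, formal charge, bond orders and heavy-atom
#' connectivity (docked poses carry no hydrogens, so donor capability is
#' inferred from valence): charged atoms are `positive`/`negative`; hydroxyl
#' and thiol-like O/S are `both`; carbonyl, ether and aromatic O/N are
#' `acceptor`; amine-like N is `both`; carbons, halogens and unknown elements
#' are `nonpolar` (unknowns with a warning).
#'
#' @param pose an `sm_pose`.
#' @return Character vector of roles, one per atom (hydrogens included, role
#'   `nonpolar`).
#' @export
type_atoms <- function(pose) {
  a <- pose$atoms
  n <- nrow(a)
  deg <- integer(n)
  maxord <- integer(n)
  b <- pose$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$from[k]; j <- b$to[k]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      maxord[i] <- max(maxord[i], b$order[k])
      maxord[j] <- max(maxord[j], b$order[k])
    }
  }
  elem <- toupper(a$elesy)
  roles <- character(n)
  known <- c("C", "N", "O", "S", "P", "H", "F", "CL", "BR", "I", "B", "SE")
  for (i in seq_len(n)) {
    e <- elem[i]
    roles[i] <-
      if (a$charge[i] > 0) "positive"
      else if (a$charge[i] < 0) "negative"
      else if (e == "O") {
        if (maxord[i] >= 2) "acceptor"          # carbonyl / oxide
        else if (deg[i] <= 1) "both"            # hydroxyl (implicit H)
        else "acceptor"                         # ether / ester oxygen
      }
      else if (e == "N") {
        if (maxord[i] >= 3) "acceptor"          # nitrile
        else if (maxord[i] == 4) "acceptor"     # aromatic
        else if (deg[i] >= 3) "acceptor"        # tertiary amine
        else "both"                             # primary/secondary amine, amide N-H
      }
      else if (e == "S") {
        if (deg[i] <= 1) "both" else "nonpolar"
      }
      else if (e %in% known) "nonpolar"
      else { warning("unknown element '", e, "'; typed nonpolar"); "nonpolar" }
  }
  roles
}

# Fixed role templates for protein atoms, keyed by residue name then atom name.
# Backbone N is a donor and backbone O an acceptor for every amino acid.
# Single-letter pseudo-residue names (DON/ACC/DAC/POS/NEG/NPL) type any atom of
# the residue and support minimal synthetic pockets.
protein_atom_roles <- function(resid, elety, elesy) {
  n <- length(resid)
  roles <- rep("nonpolar", n)
  pseudo <- c(DON = "donor", ACC = "acceptor", DAC = "both",
              POS = "positive", NEG = "negative", NPL = "nonpolar")
  side <- list(
    SER = c(OG = "both"), THR = c(OG1 = "both"), TYR = c(OH = "both"),
    CYS = c(SG = "nonpolar"), MET = c(SD = "nonpolar"),
    ASP = c(OD1 = "negative", OD2 = "negative"),
    GLU = c(OE1 = "negative", OE2 = "negative"),
    LYS = c(NZ = "positive"),
    ARG = c(NE = "positive", NH1 = "positive", NH2 = "positive"),
    HIS = c(ND1 = "both", NE2 = "both"),
    ASN = c(OD1 = "acceptor", ND2 = "donor"),
    GLN = c(OE1 = "acceptor", NE2 = "donor"),
    TRP = c(NE1 = "donor")
  )
  for (i in seq_len(n)) {
    rn <- resid[i]
    if (rn %in% names(pseudo)) { roles[i] <- pseudo[[rn]]; next }
    at <- elety[i]
    if (at == "N") roles[i] <- "donor"
    else if (at %in% c("O", "OXT")) roles[i] <- "acceptor"
    else if (!is.null(side[[rn]]) && at %in% names(side[[rn]]))
      roles[i] <- side[[rn]][[at]]
    else if (elesy[i] == "O") roles[i] <- "acceptor"
    else if (elesy[i] == "N") roles[i] <- "donor"
  }
  roles
}

#' Default piecewise linear potential parameters
#'
#' Distance knots (d1 < d2 < d3 < d4, Angstrom), well depths and clash
#' penalties (kcal/mol) for the three pair classes, plus the interaction-call
#' thresholds. The energy ramps from the clash penalty at d = 0 down to 0 at
#' d1, descends to the well depth at d2, stays flat to d3, returns to 0 at d4
#' and is 0 beyond. The H-bond and electrostatic call cutoffs equal the class
#' d4; the van der Waals call fires when the per-residue summed steric energy
#' is at or below `vdw_threshold` of the run configuration.
#'
#' @return A list of class `plp_params` with elements `steric`, `hbond`,
#'   `elec`, each `list(knots, well, clash)`.
#' @export
default_plp_params <- function() {
  structure(list(
    steric = list(knots = c(3.3, 3.6, 4.5, 6.0), well = -0.4, clash = 20),
    hbond  = list(knots = c(2.3, 2.6, 3.1, 3.4), well = -2.5, clash = 20),
    elec   = list(knots = c(2.0, 2.3, 3.2, 4.0), well = -4.0, clash = 20)
  ), class = "plp_params")
}

#' Read PLP parameters from a plain config file
#'
#' Lines of the form `class = d1,d2,d3,d4,well,clash` with class one of
#' `steric`, `hbond`, `elec`; unspecified classes keep their defaults.
#'
#' @param path path to the parameter file.
#' @return A `plp_params` list.
#' @export
read_plp_params <- function(path) {
  params <- default_plp_params()
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  for (ln in lines[nzchar(lines)]) {
    key <- trimws(sub("=.*$", "", ln))
    if (!key %in% names(params)) stop("unknown PLP pair class: ", key)
    vals <- as.numeric(strsplit(trimws(sub("^[^=]*=", "", ln)), ",")[[1]])
    if (length(vals) != 6 || any(is.na(vals))) stop("malformed PLP line: ", ln)
    if (any(diff(vals[1:4]) <= 0)) stop("PLP knots must be strictly increasing: ", key)
    if (vals[5] >= 0) stop("PLP well depth must be negative: ", key)
    params[[key]] <- list(knots = vals[1:4], well = vals[5], clash = vals[6])
  }
  params
}

#' Piecewise linear potential energy
#'
#' @param d distance(s) in Angstrom, > 0.
#' @param class_params one element of a [default_plp_params()] list
#'   (`list(knots, well, clash)`), or the name of a class.
#' @param params full `plp_params` table used when `class_params` is a name.
#' @return Energy in kcal/mol, vectorized over `d`.
#' @export
plp_energy <- function(d, class_params, params = default_plp_params()) {
  if (is.character(class_params)) class_params <- params[[class_params]]
  k <- class_params$knots; w <- class_params$well; p <- class_params$clash
  e <- numeric(length(d))
  e[d < k[1]] <- p * (k[1] - d[d < k[1]]) / k[1]
  r <- d >= k[1] & d < k[2]
  e[r] <- w * (d[r] - k[1]) / (k[2] - k[1])
  e[d >= k[2] & d <= k[3]] <- w
  r <- d > k[3] & d < k[4]
  e[r] <- w * (k[4] - d[r]) / (k[4] - k[3])
  e
}

# Pair-class partition: every (ligand atom, protein atom) pair belongs to
# exactly one PLP class. Opposite formal charges -> elec; donor/acceptor
# complementarity -> hbond; everything else -> steric.
donor_capable <- function(role) role %in% c("donor", "both", "positive")
acceptor_capable <- function(role) role %in% c("acceptor", "both", "negative")

pair_class_matrix <- function(lig_roles, prot_roles) {
  nl <- length(lig_roles); np <- length(prot_roles)
  lp <- matrix("steric", nl, np)
  ld <- donor_capable(lig_roles); la <- acceptor_capable(lig_roles)
  pd <- donor_capable(prot_roles); pa <- acceptor_capable(prot_roles)
  hb <- outer(ld, pa, "&") | outer(la, pd, "&")
  lp[hb] <- "hbond"
  lq <- ifelse(lig_roles == "positive", 1L, ifelse(lig_roles == "negative", -1L, 0L))
  pq <- ifelse(prot_roles == "positive", 1L, ifelse(prot_roles == "negative", -1L, 0L))
  el <- outer(lq, pq) < 0
  lp[el] <- "elec"
  lp
}

# site protein heavy atoms with roles, cached columns used by the callers
site_atoms <- function(structure, site) {
  a <- structure$atoms
  sel <- a$type == "ATOM" & a$res %in% site$residues & a$elesy != "H"
  if (!any(sel)) stop("empty site: no heavy atoms for the site residues")
  s <- a[sel, , drop = FALSE]
  s$role <- protein_atom_roles(s$resid, s$elety, s$elesy)
  s
}

#' Call typed protein-ligand interactions for one pose
#'
#' For each binding-site residue: a hydrogen-bond (H) event is called when a
#' donor/acceptor-complementary atom pair lies in the attractive band of the
#' H-bond potential (distance below its outer knot with favorable energy); an
#' electrostatic (E) event likewise for oppositely charged pairs under the
#' electrostatic potential; a van der Waals (V) event when the residue's
#' summed steric pair energy is at or below `vdw_threshold`. At most one event
#' per (residue, type); H/E events keep the best-energy pair, the V event's
#' geometry comes from its best steric pair while its energy is the residue
#' sum.
#'
#' @param pose an `sm_pose`, in the same frame as `structure`.
#' @param structure an `sm_structure`.
#' @param site an `sm_site` of `structure`.
#' @param params a `plp_params` table.
#' @param vdw_threshold van der Waals call threshold, kcal/mol.
#' @return Data frame of events: `compound_id`, `res`, `type` (H/E/V),
#'   `lig_atom`, `prot_atom` (row indices into the pose and structure atom
#'   tables), `distance`, `energy`, `mx`, `my`, `mz` (pair midpoint).
#' @export
call_interactions <- function(pose, structure, site, params = default_plp_params(),
                              vdw_threshold = -0.3) {
  satoms <- site_atoms(structure, site)
  a <- pose$atoms
  heavy <- which(a$elesy != "H")
  if (length(heavy) == 0) stop("pose has no heavy atoms")
  lx <- as.matrix(a[heavy, c("x", "y", "z")])
  px <- as.matrix(satoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * lx %*% t(px)
  D <- sqrt(pmax(d2, 0))
  roles <- type_atoms(pose)[heavy]
  cls <- pair_class_matrix(roles, satoms$role)
  E <- matrix(0, nrow(D), ncol(D))
  for (cl in c("steric", "hbond", "elec")) {
    m <- cls == cl & D < params[[cl]]$knots[4]
    if (any(m)) E[m] <- plp_energy(D[m], params[[cl]])
  }
  prot_rows <- which(structure$atoms$type == "ATOM" &
                     structure$atoms$res %in% site$residues &
                     structure$atoms$elesy != "H")
  events <- list()
  add <- function(res, type, li, pi, dist, energy) {
    mid <- (lx[li, ] + px[pi, ]) / 2
    events[[length(events) + 1L]] <<- data.frame(
      compound_id = pose$compound_id, res = res, type = type,
      lig_atom = heavy[li], prot_atom = prot_rows[pi],
      distance = dist, energy = energy,
      mx = mid[1], my = mid[2], mz = mid[3],
      stringsAsFactors = FALSE)
  }
  for (res in unique(satoms$res)) {
    cols <- which(satoms$res == res)
    subE <- E[, cols, drop = FALSE]
    subD <- D[, cols, drop = FALSE]
    subC <- cls[, cols, drop = FALSE]
    for (ty in c("H", "E")) {
      cl <- if (ty == "H") "hbond" else "elec"
      cand <- which(subC == cl & subE < 0, arr.ind = TRUE)
      if (nrow(cand)) {
        en <- subE[cand]
        b <- which.min(en)
        li <- cand[b, 1]; pj <- cols[cand[b, 2]]
        add(res, ty, li, pj, subD[cand[b, 1], cand[b, 2]], en[b])
      }
    }
    st <- subC == "steric"
    if (any(st)) {
      tot <- sum(subE[st])
      if (tot <= vdw_threshold) {
        stE <- ifelse(st, subE, Inf)
        b <- arrayInd(which.min(stE), dim(stE))
        add(res, "V", b[1], cols[b[2]], subD[b[1], b[2]], tot)
      }
    }
  }
  if (length(events) == 0) {
    return(data.frame(compound_id = character(0), res = character(0),
                      type = character(0), lig_atom = integer(0),
                      prot_atom = integer(0), distance = numeric(0),
                      energy = numeric(0), mx = numeric(0), my = numeric(0),
                      mz = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, events)
}

#' Total protein-ligand interaction energy of a pose
#'
#' Sum of pairwise piecewise-linear-potential energies between all ligand
#' heavy atoms and all heavy atoms of the binding-site residues, each pair
#' scored under its class (electrostatic, hydrogen-bond or steric). More
#' negative is better.
#'
#' @inheritParams call_interactions
#' @return Energy in kcal/mol.
#' @export
pose_energy <- function(pose, structure, site, params = default_plp_params()) {
  satoms <- site_atoms(structure, site)
  a <- pose$atoms
  heavy <- which(a$elesy != "H")
  lx <- as.matrix(a[heavy, c("x", "y", "z")])
  px <- as.matrix(satoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * lx %*% t(px)
  D <- sqrt(pmax(d2, 0))
  roles <- type_atoms(pose)[heavy]
  cls <- pair_class_matrix(roles, satoms$role)
  total <- 0
  for (cl in c("steric", "hbond", "elec")) {
    m <- cls == cl & D < params[[cl]]$knots[4]
    if (any(m)) total <- total + sum(plp_energy(D[m], params[[cl]]))
  }
  total
}

#' Export interaction events as TSV
#'
#' @param events event data frame from [call_interactions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
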