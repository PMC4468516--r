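#' @importFrom methods new is
NULL

# Residue identifiers are the triple (chain, resseq, icode) rendered as
# "chain:resseq[icode]"; all profile columns downstream key on this string.
residue_id <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  chain <- ifelse(is.na(chain) | chain == " ", "_", chain)
  paste0(chain, ":", resno, icode)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM and HETATM records (via bio3d), keeping original residue
#' numbering, chains and insertion codes. Alternate locations are reduced to
#' the highest-occupancy conformer. Residues are identified downstream by the
#' triple (chain, residue number, insertion code).
#'
#' @param path path to a PDB file.
#' @param id structure identifier; defaults to the file base name.
#' @return An object of class `sm_structure`: a list with `id`, `atoms`
#'   (data frame with columns `type`, `elety`, `elesy`, `resid`, `chain`,
#'   `resno`, `icode`, `res`, `x`, `y`, `z`, `o`) and `source`. `res` is the
#'   residue-identifier string.
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  atoms <- data.frame(
    type = at$type,
    elety = at$elety,
    elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                   guess_element(at$elety), at$elesy),
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "_", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  if (!any(atoms$type == "ATOM")) stop("no protein residues in ", path)
  atoms$res <- residue_id(atoms$chain, atoms$resno, atoms$icode)
  # alternate locations: keep the highest-occupancy copy of each atom
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(atoms$res, atoms$elety, atoms$type)
    ord <- order(key, -atoms$o)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  rownames(atoms) <- NULL
  structure(list(id = if (is.null(id)) sub("\\.pdb$", "", basename(path)) else id,
                 atoms = atoms, source = path),
            class = "sm_structure")
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA"), two, one)
}

#' Write a protein structure to a PDB file
#'
#' @param structure an `sm_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "sm_structure"))
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   type = a$type,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno,
                   resid = a$resid,
                   chain = ifelse(a$chain == "_", "", a$chain),
                   insert = a$icode,
                   eleno = seq_len(nrow(a)),
                   elety = a$elety,
                   o = a$o, b = rep(0, nrow(a)),
                   elesy = a$elesy)
  invisible(path)
}

#' Extract a bound ligand from a structure as a pose
#'
#' Pulls the HETATM atoms of a named residue (e.g. the ATP analog ANP) out of a
#' structure, for use as the reference ligand of [define_binding_site()].
#'
#' @param structure an `sm_structure`.
#' @param resname HETATM residue name of the ligand.
#' @return An `sm_pose` (without bonds or energy).
#' @export
extract_ligand <- function(structure, resname) {
  a <- structure$atoms
  sel <- a$type == "HETATM" & a$resid == resname
  if (!any(sel)) stop("no HETATM residue named '", resname, "' in ", structure$id)
  new_pose(compound_id = resname, protein_id = structure$id,
           atoms = data.frame(elesy = a$elesy[sel], charge = 0,
                              x = a$x[sel], y = a$y[sel], z = a$z[sel],
                              stringsAsFactors = FALSE),
           bonds = data.frame(from = integer(0), to = integer(0), order = integer(0)))
}

new_pose <- function(compound_id, protein_id = NA_character_, atoms, bonds,
                     energy = NA_real_) {
  heavy <- atoms$elesy != "H"
  structure(list(compound_id = compound_id, protein_id = protein_id,
                 atoms = atoms, bonds = bonds, energy = energy,
                 M = sum(heavy)),
            class = "sm_pose")
}

pose_xyz <- function(pose, heavy_only = TRUE) {
  a <- pose$atoms
  if (heavy_only) a <- a[a$elesy != "H", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Define a binding site around a reference ligand
#'
#' A protein residue belongs to the site iff the minimum heavy-atom distance
#' between any of its atoms and any heavy atom of the reference ligand is at
#' most `radius` (inclusive). Hydrogens are ignored on both sides.
#'
#' @param structure an `sm_structure` (must be in the same frame as the ligand).
#' @param ref_ligand an `sm_pose` giving the reference ligand geometry.
#' @param radius inclusion cutoff in Angstrom.
#' @return An `sm_site`: list with `protein_id`, `residues` (character vector of
#'   residue ids, in chain/sequence order), `ref_ligand_id`, `radius`.
#' @export
define_binding_site <- function(structure, ref_ligand, radius = 10.0) {
  stopifnot(inherits(structure, "sm_structure"), inherits(ref_ligand, "sm_pose"))
  if (radius <= 0) stop("radius must be > 0")
  lig <- pose_xyz(ref_ligand)
  if (nrow(lig) == 0) stop("reference ligand has no heavy atoms")
  a <- structure$atoms
  prot <- a[a$type == "ATOM" & a$elesy != "H", , drop = FALSE]
  if (nrow(prot) == 0) stop("no protein heavy atoms in ", structure$id)
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(pxyz^2), rowSums(lig^2), "+") - 2 * pxyz %*% t(lig)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  keep <- tapply(mind, prot$res, min) <= radius
  res_in <- names(keep)[keep]
  if (length(res_in) == 0) stop("empty binding site: no residue within ",
                                radius, " A of the reference ligand")
  # preserve structure order
  ordered <- unique(prot$res)
  res_in <- ordered[ordered %in% res_in]
  structure(list(protein_id = structure$id, residues = res_in,
                 ref_ligand_id = ref_ligand$compound_id, radius = radius),
            class = "sm_site")
}

# alpha-carbon (or single-atom) coordinates for a set of residue ids
residue_anchor_xyz <- function(structure, res_ids) {
  a <- structure$atoms
  out <- matrix(NA_real_, length(res_ids), 3)
  for (i in seq_along(res_ids)) {
    sel <- a$res == res_ids[i]
    if (!any(sel)) stop("residue not found in ", structure$id, ": ", res_ids[i])
    sub <- a[sel, , drop = FALSE]
    j <- match("CA", sub$elety)
    if (is.na(j)) j <- 1L
    out[i, ] <- c(sub$x[j], sub$y[j], sub$z[j])
  }
  out
}

#' Least-squares (Kabsch) superposition of one structure onto another
#'
#' Given a user-supplied residue correspondence, computes the rigid transform
#' minimizing the RMSD over paired alpha-carbons (falling back to the first
#' atom of single-atom residues) and applies it to all atoms of the mobile
#' structure.
#'
#' @param mobile,reference `sm_structure` objects.
#' @param correspondence two-column data frame (or matrix) of residue-id pairs
#'   `(mobile, reference)`, or path to a two-column TSV of the same.
#' @return A list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the paired guide atoms) and `structure` (the transformed
#'   mobile `sm_structure`). Transformed coordinates are
#'   `x' = R x + t`.
#' @export
superimpose <- function(mobile, reference, correspondence) {
  if (is.character(correspondence) && length(correspondence) == 1) {
    correspondence <- utils::read.table(correspondence, header = FALSE, sep = "\t",
                                        col.names = c("mobile", "reference"),
                                        colClasses = "character")
  }
  correspondence <- as.data.frame(correspondence, stringsAsFactors = FALSE)
  if (ncol(correspondence) < 2) stop("correspondence must have two columns")
  if (nrow(correspondence) < 3) stop("underdetermined superposition: need >= 3 residue pairs")
  X <- residue_anchor_xyz(mobile, as.character(correspondence[[1]]))
  Y <- residue_anchor_xyz(reference, as.character(correspondence[[2]]))
  fit <- kabsch(X, Y)
  if (is.null(fit)) stop("underdetermined superposition: paired points are collinear")
  out <- mobile
  xyz <- as.matrix(mobile$atoms[, c("x", "y", "z")])
  new_xyz <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
  out$atoms$x <- new_xyz[, 1]; out$atoms$y <- new_xyz[, 2]; out$atoms$z <- new_xyz[, 3]
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, structure = out)
}

# Kabsch algorithm via SVD; returns NULL when the point sets are collinear
# (second singular value of the centered cloud ~ 0) and the rotation is
# underdetermined.
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  sv_x <- svd(X0)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1)) return(NULL)
  H <- t(X0) %*% Y0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - as.numeric(R %*% cx)
  fitted <- sweep(X %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

# decode V2000 old-style charge codes (field 4 of the atom line):
# 0 none, 1..3 = +3..+1, 4 radical, 5..7 = -1..-3
decode_sdf_charge <- function(code) {
  code <- ifelse(is.na(code), 0, code)
  ifelse(code == 0 | code == 4, 0L, 4L - as.integer(code))
}
encode_sdf_charge <- function(charge) {
  ifelse(charge == 0, 0L, 4L - as.integer(charge))
}

#' Read docked ligand poses from an SDF or MOL2 file
#'
#' One pose per record. For SDF, the docked energy is taken from the data field
#' named by `energy_field` when present; formal charges from the atom-block
#' charge column. For MOL2, per-atom charges are rounded to the nearest integer
#' to obtain formal charges. Records without usable 3D coordinates (all
#' coordinates zero or missing) are skipped with a warning.
#'
#' @param path path to a multi-record SDF (V2000) or MOL2 file.
#' @param format `"auto"` (by extension), `"sdf"` or `"mol2"`.
#' @param energy_field SDF data field holding the docked energy, kcal/mol.
#' @param protein_id optional protein id stamped on every pose.
#' @return A list of `sm_pose` objects. Each pose has `compound_id`,
#'   `atoms` (element, formal charge, x, y, z), `bonds` (from, to, order),
#'   `energy` (NA when absent) and `M` (heavy-atom count).
#' @export
read_poses <- function(path, format = c("auto", "sdf", "mol2"),
                       energy_field = "GEMDOCK_ENERGY", protein_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("pose file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  }
  poses <- if (format == "sdf") read_poses_sdf(path, energy_field, protein_id)
           else read_poses_mol2(path, protein_id)
  if (length(poses) == 0) stop("no valid pose records in ", path)
  poses
}

read_poses_sdf <- function(path, energy_field, protein_id) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok)) warning(sum(!ok), " corrupt SDF record(s) skipped in ", path)
  sdfset <- sdfset[ok]
  poses <- list()
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || nrow(ab) == 0) next
    xyz <- ab[, 1:3, drop = FALSE]
    if (all(abs(xyz) < 1e-8) || any(!is.finite(xyz))) {
      warning("record ", i, " in ", path, " lacks 3D coordinates; skipped")
      next
    }
    elem <- sub("_.*$", "", rownames(ab))
    charge <- if (ncol(ab) >= 4) decode_sdf_charge(ab[, 4]) else rep(0L, nrow(ab))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(bb) || nrow(bb) == 0) {
      data.frame(from = integer(0), to = integer(0), order = integer(0))
    } else {
      data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    }
    db <- ChemmineR::datablock(sdf)
    energy <- NA_real_
    if (length(db) && energy_field %in% names(db)) {
      energy <- suppressWarnings(as.numeric(db[[energy_field]]))
    }
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- paste0("mol", i)
    poses[[length(poses) + 1L]] <- new_pose(
      compound_id = nm, protein_id = protein_id,
      atoms = data.frame(elesy = elem, charge = charge,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE),
      bonds = bonds, energy = energy)
  }
  poses
}

read_poses_mol2 <- function(path, protein_id) {
  mols <- bio3d::read.mol2(path)
  if (inherits(mols, "mol2")) mols <- list(mols)
  poses <- list()
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    at <- m$atom
    if (is.null(at) || nrow(at) == 0) next
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (all(abs(xyz) < 1e-8) || any(!is.finite(xyz))) {
      warning("record ", i, " in ", path, " lacks 3D coordinates; skipped")
      next
    }
    elem <- toupper(sub("\\..*$", "", at$elena))
    charge <- if (!is.null(at$charge)) as.integer(round(at$charge)) else rep(0L, nrow(at))
    bd <- m$bond
    bonds <- if (is.null(bd) || nrow(bd) == 0) {
      data.frame(from = integer(0), to = integer(0), order = integer(0))
    } else {
      ord <- suppressWarnings(as.integer(bd$type))
      ord[is.na(ord)] <- ifelse(bd$type[is.na(ord)] == "ar", 4L, 1L)
      data.frame(from = as.integer(bd$origin), to = as.integer(bd$target), order = ord)
    }
    nm <- if (!is.null(m$name) && nzchar(m$name)) m$name else paste0("mol", i)
    poses[[length(poses) + 1L]] <- new_pose(
      compound_id = nm, protein_id = protein_id,
      atoms = data.frame(elesy = elem, charge = charge,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE),
      bonds = bonds, energy = NA_real_)
  }
  poses
}

#' Write ligand poses to a multi-record SDF file
#'
#' Formal charges are stored in the atom-block charge column (V2000 codes);
#' the docked energy, when set, in the data field named by `energy_field`.
#'
#' @param poses list of `sm_pose` objects.
#' @param path output path.
#' @param energy_field SDF data field name for the docked energy.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path, energy_field = "GEMDOCK_ENERGY") {
  sdfs <- lapply(poses, function(p) {
    a <- p$atoms
    ab <- cbind(C1 = a$x, C2 = a$y, C3 = a$z, C5 = encode_sdf_charge(a$charge))
    rownames(ab) <- paste(a$elesy, seq_len(nrow(a)), sep = "_")
    b <- p$bonds
    bb <- cbind(C1 = b$from, C2 = b$to, C3 = b$order)
    rownames(bb) <- as.character(seq_len(nrow(b)))
    db <- character(0)
    if (!is.na(p$energy)) db <- stats::setNames(format(p$energy), energy_field)
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = c(Molecule_Name = p$compound_id, Source = "sitemoiety",
                            Comment = "",
                            Counts_Line = sprintf("%3d%3d  0  0  0  0            999 V2000",
                                                  nrow(a), nrow(b))),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  ids <- vapply(poses, function(p) p$compound_id, character(1))
  sdfset <- methods::new(methods::getClass("SDFset", where = asNamespace("ChemmineR")),
                         SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(sdfset, file = path, cid = TRUE)
  invisible(path)
}

#' @export
print.sm_structure <- function(x, ...) {
  cat("<sm_structure>", x$id, "-", length(unique(x$atoms$res)), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' @export
print.sm_site <- function(x, ...) {
  cat("<sm_site>", x$protein_id, "-", length(x$residues), "residues within",
      x$radius, "A of", x$ref_ligand_id, "\n")
  invisible(x)
}

#' @export
print.sm_pose <- function(x, ...) {
  cat("<sm_pose>", x$compound_id, "- M =", x$M,
      if (!is.na(x$energy)) paste0("E = ", format(x$energy), " kcal/mol") else "", "\n")
  invisible(x)
}
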