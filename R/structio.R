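# Structure containers and PDB I/O.
#
# A `pdb_structure` is a light wrapper around a flat atom table: one row per
# heavy atom, coordinates in Angstrom, residue numbering taken verbatim from
# the source PDB (1-based, gaps allowed, never renumbered). Hydrogens are
# dropped on read; the geometric salt-bridge criterion and all burial /
# flexibility measures in this package are defined on heavy atoms only.

AMINO3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

ATOM_COLS <- c("serial", "name", "element", "resname", "chain", "resnum",
               "inscode", "altloc", "occupancy", "x", "y", "z", "is_protein")

#' Build a structure from an atom table
#'
#' @param atoms data.frame with columns serial, name, element, resname,
#'   chain, resnum, inscode, altloc, occupancy, x, y, z and logical
#'   is_protein. Rows are sorted by (chain, resnum, inscode).
#' @param id identifier string.
#' @return An object of class `pdb_structure`.
#' @export
new_structure <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms), all(ATOM_COLS %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1]")
  if (any(!nzchar(atoms$name))) stop("empty atom name")
  ord <- order(atoms$chain, atoms$resnum, atoms$inscode,
               match(atoms$serial, atoms$serial))
  atoms <- atoms[ord, ATOM_COLS, drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pdb_structure '%s': %d atoms, %d residues, chains %s>\n",
              x$id, nrow(a), nrow(unique(a[, c("chain", "resnum", "inscode")])),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

is_structure <- function(x) inherits(x, "pdb_structure")
is_ensemble  <- function(x) inherits(x, "pdb_ensemble")

#' Build an ensemble from frames sharing one topology
#'
#' @param frames list of `pdb_structure`, identical atom ordering
#'   (chain/resnum/name) in every frame.
#' @param frame_interval informational time between frames.
#' @return `pdb_ensemble` object.
#' @export
new_ensemble <- function(frames, frame_interval = NA_real_) {
  stopifnot(length(frames) >= 1L, all(vapply(frames, is_structure, logical(1))))
  key <- function(s) paste(s$atoms$chain, s$atoms$resnum, s$atoms$inscode,
                           s$atoms$name)
  k1 <- key(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!identical(key(frames[[i]]), k1))
      stop("frame ", i, " has mismatched topology")
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "pdb_ensemble")
}

#' @export
print.pdb_ensemble <- function(x, ...) {
  cat(sprintf("<pdb_ensemble: %d frames x %d atoms>\n",
              length(x$frames), nrow(x$frames[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.pdb_ensemble <- function(x) length(x$frames)

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Per-chain one-letter sequence of a structure
#'
#' @param structure `pdb_structure`.
#' @param chain chain id; default first chain.
#' @return character scalar, one letter per amino-acid residue.
#' @export
structure_sequence <- function(structure, chain = NULL) {
  a <- structure$atoms[structure$atoms$is_protein, , drop = FALSE]
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  res <- unique(a[, c("resnum", "inscode", "resname")])
  letters1 <- AMINO3[res$resname]
  paste(letters1[!is.na(letters1)], collapse = "")
}

#' Residue table of a structure
#'
#' One row per residue: chain, resnum, inscode, resname.
#' @param structure `pdb_structure`.
#' @param protein_only drop waters/ligands (default TRUE).
#' @export
residue_table <- function(structure, protein_only = TRUE) {
  a <- structure$atoms
  if (protein_only) a <- a[a$is_protein, , drop = FALSE]
  out <- unique(a[, c("chain", "resnum", "inscode", "resname")])
  rownames(out) <- NULL
  out
}

# atoms of one residue
residue_atoms <- function(structure, chain, resnum, inscode = "") {
  a <- structure$atoms
  a[a$chain == chain & a$resnum == resnum & a$inscode == inscode, ,
    drop = FALSE]
}

apply_altloc_policy <- function(atoms, policy = c("keep-first", "keep-all")) {
  policy <- match.arg(policy)
  if (policy == "keep-all" || all(atoms$altloc == "")) return(atoms)
  # keep, per (chain, resnum, inscode, name), the highest-occupancy altloc;
  # ties broken by altloc letter
  key <- paste(atoms$chain, atoms$resnum, atoms$inscode, atoms$name)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resnum,
                                   atoms$inscode, atoms$name)), , drop = FALSE]
  atoms
}

#' Read a PDB file into a structure or ensemble
#'
#' Single-model files give a `pdb_structure`; files with MODEL/ENDMDL blocks
#' give a `pdb_ensemble` (frames must share topology). HETATM waters and
#' ligands are retained but flagged `is_protein = FALSE` and excluded from
#' every geometric operation. Hydrogens are dropped.
#'
#' @param path PDB file.
#' @param altloc_policy "keep-first" keeps, for each atom name in a residue,
#'   the alternate location with the highest occupancy (ties by altloc
#'   letter); "keep-all" keeps every altloc row.
#' @return `pdb_structure` or `pdb_ensemble`.
#' @export
read_pdb <- function(path, altloc_policy = c("keep-first", "keep-all")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file: ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("PDB file contains zero atoms")
  blank <- function(v) ifelse(is.na(v), "", v)
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = blank(at$elesy),
    resname = at$resid,
    chain = blank(at$chain),
    resnum = at$resno,
    inscode = blank(at$insert),
    altloc = blank(at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z,
    is_protein = at$resid %in% names(AMINO3) & at$type == "ATOM",
    stringsAsFactors = FALSE)
  is_h <- toupper(atoms$element) == "H" | grepl("^[0-9]*H", atoms$name)
  atoms <- atoms[!is_h, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("PDB file contains zero heavy atoms")
  atoms <- apply_altloc_policy(atoms, altloc_policy)
  nframes <- nrow(pdb$xyz)
  id <- sub("\\.pdb$", "", basename(path))
  if (nframes <= 1L) return(new_structure(atoms, id = id))
  # map retained atoms back to columns of the xyz matrix by original row
  row_idx <- match(atoms$serial, at$eleno)
  frames <- lapply(seq_len(nframes), function(f) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
    af <- atoms
    af$x <- xyz[row_idx, 1L]; af$y <- xyz[row_idx, 2L]; af$z <- xyz[row_idx, 3L]
    new_structure(af, id = sprintf("%s_model%d", id, f))
  })
  new_ensemble(frames)
}

#' Write a structure or ensemble to PDB
#'
#' Round-trips through [read_pdb()] preserving atom names, residue numbering
#' and coordinates to 3 decimals (PDB fixed width).
#'
#' @param x `pdb_structure` or `pdb_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (is_ensemble(x)) {
    a <- x$frames[[1L]]$atoms
    xyz <- do.call(rbind, lapply(x$frames, function(s) as.vector(t(coords(s)))))
  } else if (is_structure(x)) {
    a <- x$atoms
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1L)
  } else stop("not a pdb_structure or pdb_ensemble")
  if (nrow(a) == 0L) stop("empty structure")
  if (any(xyz >= 1e4 | xyz <= -1e3))
    stop("coordinates exceed PDB fixed-width field")
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(a$is_protein, "ATOM", "HETATM"),
    resno = a$resnum, resid = a$resname, eleno = a$serial, elety = a$name,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$inscode == "", "", a$inscode),
    alt = ifelse(a$altloc == "", "", a$altloc),
    o = a$occupancy, b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(path)
}

#' Count protein heavy atoms near a point
#'
#' Burial proxy used by the titration model: the number of protein heavy
#' atoms within `radius` of `center`, excluding atoms exactly at the center.
#'
#' @param structure `pdb_structure`.
#' @param center numeric length-3 (Angstrom).
#' @param radius Angstrom, > 0.
#' @return integer count.
#' @export
neighbor_count <- function(structure, center, radius) {
  stopifnot(radius > 0, length(center) == 3L)
  a <- structure$atoms[structure$atoms$is_protein, , drop = FALSE]
  if (nrow(a) == 0L) return(0L)
  d2 <- (a$x - center[1L])^2 + (a$y - center[2L])^2 + (a$z - center[3L])^2
  sum(d2 <= radius^2 & d2 > 0)
}

#' Matthews coefficient and solvent content of a crystal
#'
#' Computes the unit-cell volume from cell dimensions, the Matthews
#' coefficient VM = V / (Z * mass) in cubic Angstrom per Dalton, and the
#' solvent fraction 1 - 1.66 * vbar / VM.
#'
#' @param cell_a,cell_b,cell_c cell edges, Angstrom.
#' @param alpha,beta,gamma cell angles, degrees.
#' @param z copies of the molecule per unit cell.
#' @param protein_mass molecular mass, Dalton.
#' @param vbar partial specific volume, cm^3/g (protein default 0.74).
#' @return list of class `crystal_packing` with cell volume, `vm` and
#'   `solvent_fraction`.
#' @export
crystal_packing <- function(cell_a, cell_b, cell_c,
                            alpha = 90, beta = 90, gamma = 90,
                            z = 1, protein_mass, vbar = 0.74) {
  stopifnot(cell_a > 0, cell_b > 0, cell_c > 0, z >= 1, protein_mass > 0,
            all(c(alpha, beta, gamma) > 0), all(c(alpha, beta, gamma) < 180))
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  vol <- cell_a * cell_b * cell_c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  vm <- vol / (z * protein_mass)
  if (vm <= 0) stop("non-positive Matthews coefficient")
  structure(list(cell_a = cell_a, cell_b = cell_b, cell_c = cell_c,
                 alpha = alpha, beta = beta, gamma = gamma, z = z,
                 protein_mass = protein_mass, volume = vol, vm = vm,
                 vbar = vbar,
                 solvent_fraction = matthews_solvent_fraction(vm, vbar)),
            class = "crystal_packing")
}

#' Solvent fraction from a Matthews coefficient
#'
#' @param vm Matthews coefficient, cubic Angstrom per Dalton.
#' @param vbar partial specific volume, cm^3/g.
#' @return solvent fraction in (0, 1) for vm > 1.66 * vbar.
#' @export
matthews_solvent_fraction <- function(vm, vbar = 0.74) {
  stopifnot(vm > 0, vbar > 0)
  1 - (1.66 * vbar) / vm
}
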