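# Synthetic ground-truth generators: toy helical structures with planted
# charged pairs, MD-like jittered ensembles, first-order decay series and
# Michaelis-Menten rate tables. Every generator is a pure function of its
# arguments plus one integer seed; no global RNG state leaks.

# canonical distance (Angstrom) from CA to the charged side-chain atoms,
# measured along the CA->CB direction
CHARGED_ATOM_GEOM <- list(
  ARG = list(atoms = c("NH1", "NH2"), dist = 4.1),
  LYS = list(atoms = "NZ",            dist = 4.7),
  HIS = list(atoms = c("ND1", "NE2"), dist = 3.6),
  ASP = list(atoms = c("OD1", "OD2"), dist = 2.9),
  GLU = list(atoms = c("OE1", "OE2"), dist = 3.9))

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ideal alpha-helix backbone: CA on a helix of radius 2.3 A, rise 1.5 A,
# 100 degrees per residue; N and C interpolated, O offset from C, CB radial.
helix_backbone <- function(n, chain = "A", z0 = 0) {
  r <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  t <- (seq_len(n) - 1L)
  ca <- cbind(r * cos(t * twist), r * sin(t * twist), z0 + t * rise)
  ca
}

unit <- function(v) v / sqrt(sum(v^2))

# place residue atoms for one residue: backbone N, CA, C, O, CB (except GLY)
toy_residue_atoms <- function(resname, chain, resnum, ca, axis_point) {
  outward <- unit(c(ca[1L] - axis_point[1L], ca[2L] - axis_point[2L], 0))
  up <- c(0, 0, 1)
  n_at  <- ca + 1.46 * unit(-0.5 * up - outward * 0.5)
  c_at  <- ca + 1.52 * unit(0.5 * up - outward * 0.5)
  o_at  <- c_at + 1.23 * unit(outward * 0.2 + up * 0.8)
  cb    <- ca + 1.53 * outward
  names <- c("N", "CA", "C", "O")
  xyz <- rbind(n_at, ca, c_at, o_at)
  if (resname != "GLY") {
    names <- c(names, "CB")
    xyz <- rbind(xyz, cb)
  }
  data.frame(name = names, resname = resname, chain = chain, resnum = resnum,
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

finish_atoms <- function(df, id) {
  atoms <- data.frame(
    serial = seq_len(nrow(df)), name = df$name, element = substr(df$name, 1, 1),
    resname = df$resname, chain = df$chain, resnum = df$resnum,
    inscode = "", altloc = "", occupancy = 1,
    x = df$x, y = df$y, z = df$z, is_protein = TRUE,
    stringsAsFactors = FALSE)
  new_structure(atoms, id = id)
}

#' Generate a toy helical structure with planted charged pairs
#'
#' Builds an ideal poly-alanine helix and converts selected residue pairs to
#' oppositely charged types, placing the side-chain charged atoms so that the
#' minimum N-O distance of each planted pair equals its target to within
#' 0.05 Angstrom. Only the charged-atom geometry matters to the salt-bridge
#' criterion, so no rotamer sampling is attempted: basic side chains point
#' along the CA->CB direction at canonical distances and the acidic partner's
#' carboxylate oxygens are placed on the line towards its own CA so the
#' closest approach is exactly the target.
#'
#' @param n_residues residues in the helix (single chain "A").
#' @param planted_pairs data.frame with columns `basic` (ARG/LYS/HIS),
#'   `acidic` (ASP/GLU), `distance` (target minimum N-O distance, Angstrom,
#'   > 2); one pair is planted per row. NULL plants none.
#' @param spacing residues between consecutive planted pairs (default 8,
#'   keeps pairs from interfering).
#' @param seed unused randomness hook, kept for interface symmetry.
#' @return `pdb_structure`.
#' @export
make_toy_structure <- function(n_residues = 30, planted_pairs = NULL,
                               spacing = 8, seed = 1) {
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("basic", "acidic", "distance") %in% names(planted_pairs)))
    if (any(planted_pairs$distance <= 2.0))
      stop("infeasible planted distance (<= 2 Angstrom)")
    if (!all(planted_pairs$basic %in% c("ARG", "LYS", "HIS")))
      stop("basic residue must be ARG, LYS or HIS")
    if (!all(planted_pairs$acidic %in% c("ASP", "GLU")))
      stop("acidic residue must be ASP or GLU")
    need <- nrow(planted_pairs) * spacing + 4L
    if (n_residues < need) n_residues <- need
  }
  ca <- helix_backbone(n_residues)
  resnames <- rep("ALA", n_residues)
  basic_at <- vector("list", n_residues)  # extra side-chain atoms per residue
  if (!is.null(planted_pairs)) {
    for (k in seq_len(nrow(planted_pairs))) {
      i <- (k - 1L) * spacing + 2L       # basic residue
      j <- i + 2L                        # acidic residue
      b <- planted_pairs$basic[k]; a <- planted_pairs$acidic[k]
      d <- planted_pairs$distance[k]
      resnames[i] <- b; resnames[j] <- a
      gb <- CHARGED_ATOM_GEOM[[b]]
      dir_b <- unit(c(ca[i, 1L], ca[i, 2L], 0))   # outward = CA->CB direction
      pos_b <- t(vapply(seq_along(gb$atoms), function(m)
        ca[i, ] + (gb$dist + 0.3 * (m - 1L)) * dir_b, numeric(3L)))
      basic_at[[i]] <- data.frame(name = gb$atoms, resname = b, chain = "A",
                                  resnum = i, x = pos_b[, 1L], y = pos_b[, 2L],
                                  z = pos_b[, 3L], stringsAsFactors = FALSE)
      # closest basic charged atom anchors the acid placement
      ref <- pos_b[1L, ]
      ga <- CHARGED_ATOM_GEOM[[a]]
      dir_a <- unit(ca[j, ] - ref)       # towards the acid's own CA
      o1 <- ref + d * dir_a
      o2 <- o1 + 2.2 * dir_a             # second carboxylate O, farther away
      basic_at[[j]] <- data.frame(name = ga$atoms[1:2],
                                  resname = a, chain = "A", resnum = j,
                                  x = c(o1[1L], o2[1L]), y = c(o1[2L], o2[2L]),
                                  z = c(o1[3L], o2[3L]),
                                  stringsAsFactors = FALSE)
    }
  }
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    df <- toy_residue_atoms(resnames[i], "A", i, ca[i, ],
                            axis_point = c(0, 0, ca[i, 3L]))
    if (!is.null(basic_at[[i]])) df <- rbind(df, basic_at[[i]])
    rows[[i]] <- df
  }
  finish_atoms(do.call(rbind, rows), id = "toy_helix")
}

#' Gaussian-jittered conformational ensemble
#'
#' Emulates MD snapshots: each frame displaces every atom independently by an
#' isotropic Gaussian whose standard deviation is the sigma of the atom's
#' residue. With per-atom displacement sd sigma in each coordinate, the
#' expected per-residue RMSF is sigma * sqrt(3).
#'
#' @param structure reference `pdb_structure`.
#' @param sigma scalar sd (Angstrom) or vector with one sd per residue (in
#'   residue-table order).
#' @param n_frames number of frames, >= 1.
#' @param seed integer seed; identical seeds give identical ensembles.
#' @param keep_reference if TRUE, frame 1 is the unperturbed reference.
#' @return `pdb_ensemble`.
#' @export
jitter_ensemble <- function(structure, sigma, n_frames, seed = 1,
                            keep_reference = FALSE) {
  stopifnot(is_structure(structure), all(sigma >= 0), n_frames >= 1)
  res <- residue_table(structure, protein_only = FALSE)
  if (length(sigma) == 1L) sigma <- rep(sigma, nrow(res))
  if (length(sigma) != nrow(res))
    stop("sigma must be scalar or one value per residue")
  akey <- paste(structure$atoms$chain, structure$atoms$resnum,
                structure$atoms$inscode)
  rkey <- paste(res$chain, res$resnum, res$inscode)
  atom_sigma <- sigma[match(akey, rkey)]
  n_atoms <- nrow(structure$atoms)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      s <- structure
      if (!(keep_reference && f == 1L)) {
        disp <- matrix(stats::rnorm(3L * n_atoms, sd = rep(atom_sigma, 3L)),
                       ncol = 3L)
        s$atoms$x <- s$atoms$x + disp[, 1L]
        s$atoms$y <- s$atoms$y + disp[, 2L]
        s$atoms$z <- s$atoms$z + disp[, 3L]
      }
      s$id <- sprintf("%s_frame%d", structure$id, f)
      s
    })
  })
  new_ensemble(frames)
}

#' Simulate a first-order activity-decay series
#'
#' activity(t) = A0 * exp(-(ln 2 / half_life) * t) * (1 + eps),
#' eps ~ Normal(0, noise_sd). Multiplicative noise: spectrophotometric error
#' scales with signal.
#'
#' @param half_life minutes, > 0.
#' @param timepoints minutes, non-negative increasing.
#' @param initial_activity arbitrary units.
#' @param noise_sd relative noise sd.
#' @param seed integer seed.
#' @return data.frame (time, activity).
#' @export
simulate_decay <- function(half_life, timepoints = seq(0, 60, by = 5),
                           initial_activity = 100, noise_sd = 0, seed = 1) {
  stopifnot(half_life > 0, all(timepoints >= 0), !is.unsorted(timepoints),
            noise_sd >= 0)
  kd <- log(2) / half_life
  mu <- initial_activity * exp(-kd * timepoints)
  eps <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(timepoints), sd = noise_sd)) else 0
  data.frame(time = timepoints, activity = mu * (1 + eps))
}

#' Simulate Michaelis-Menten initial rates
#'
#' rate = kcat * E * S / (KM + S) * (1 + eps), eps ~ Normal(0, noise_sd).
#'
#' @param km Michaelis constant, micromolar.
#' @param kcat turnover number, per second.
#' @param enzyme_conc enzyme concentration, micromolar.
#' @param substrate_levels substrate concentrations, micromolar. Default is
#'   a ladder over the 50-2000 micromolar assay range.
#' @param noise_sd relative noise sd.
#' @param seed integer seed.
#' @return data.frame (substrate, rate) in micromolar and micromolar/s.
#' @export
simulate_mm <- function(km, kcat, enzyme_conc = 0.02,
                        substrate_levels = c(50, 100, 200, 400, 800,
                                             1200, 1600, 2000),
                        noise_sd = 0, seed = 1) {
  stopifnot(km > 0, kcat > 0, enzyme_conc > 0, all(substrate_levels > 0),
            noise_sd >= 0)
  mu <- kcat * enzyme_conc * substrate_levels / (km + substrate_levels)
  eps <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(substrate_levels), sd = noise_sd))
  else 0
  data.frame(substrate = substrate_levels, rate = mu * (1 + eps))
}
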