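# Trajectory-style flexibility metrics over conformational ensembles:
# backbone RMSD of each frame against a reference, and per-residue RMSF
# about the ensemble mean.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

backbone_coords <- function(structure) {
  a <- structure$atoms[structure$atoms$is_protein &
                       structure$atoms$name %in% BACKBONE_NAMES, ,
                       drop = FALSE]
  list(key = paste(a$chain, a$resnum, a$inscode, a$name),
       xyz = as.matrix(a[, c("x", "y", "z")]),
       residue = paste(a$chain, a$resnum, a$inscode))
}

#' Backbone RMSD of every frame against a reference
#'
#' Per frame, optionally Kabsch-superposes the backbone (N, CA, C, O atoms)
#' onto the reference, then reports the RMSD over those atoms.
#'
#' @param ensemble `pdb_ensemble`.
#' @param reference `pdb_structure` sharing backbone topology.
#' @param superpose_each superpose each frame first (default TRUE).
#' @return list of class `rmsd_series`: `frame`, `rmsd` (Angstrom),
#'   `mean_rmsd`.
#' @export
backbone_rmsd_series <- function(ensemble, reference, superpose_each = TRUE) {
  stopifnot(is_ensemble(ensemble), is_structure(reference))
  ref <- backbone_coords(reference)
  if (nrow(ref$xyz) == 0L) stop("reference has no backbone atoms")
  rmsd <- vapply(ensemble$frames, function(s) {
    fr <- backbone_coords(s)
    if (!identical(fr$key, ref$key)) {
      missing <- unique(c(setdiff(ref$key, fr$key), setdiff(fr$key, ref$key)))
      stop("backbone mismatch at: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    xyz <- fr$xyz
    if (superpose_each) {
      sp <- superpose(ref$xyz, xyz)
      xyz <- sweep(xyz %*% t(sp$rotation), 2L, sp$translation, "+")
    }
    sqrt(mean(rowSums((xyz - ref$xyz)^2)))
  }, numeric(1L))
  structure(list(frame = seq_along(rmsd), rmsd = rmsd,
                 mean_rmsd = mean(rmsd)), class = "rmsd_series")
}

#' Per-residue RMSF of an ensemble
#'
#' RMSF_i = sqrt(mean over frames of squared displacement of residue i's
#' C-alpha from its ensemble-mean position), after optionally superposing
#' every frame onto the ensemble mean (one refinement pass: frames are first
#' aligned to frame 1, the mean is formed, then frames are re-aligned to
#' that mean).
#'
#' @param ensemble `pdb_ensemble` with >= 2 frames.
#' @param align_to_mean superpose frames first (default TRUE).
#' @return data.frame: chain, resnum, rmsf (Angstrom).
#' @export
per_residue_rmsf <- function(ensemble, align_to_mean = TRUE) {
  stopifnot(is_ensemble(ensemble))
  if (length(ensemble$frames) < 2L) stop("RMSF needs at least 2 frames")
  mats <- lapply(ensemble$frames, function(s) {
    a <- s$atoms[s$atoms$is_protein & s$atoms$name == "CA", , drop = FALSE]
    list(xyz = as.matrix(a[, c("x", "y", "z")]),
         chain = a$chain, resnum = a$resnum)
  })
  xyzs <- lapply(mats, `[[`, "xyz")
  if (align_to_mean) {
    align_all <- function(target)
      lapply(xyzs, function(x) {
        sp <- superpose(target, x)
        sweep(x %*% t(sp$rotation), 2L, sp$translation, "+")
      })
    xyzs <- align_all(xyzs[[1L]])
    mean1 <- Reduce(`+`, xyzs) / length(xyzs)
    xyzs <- align_all(mean1)
  }
  mu <- Reduce(`+`, xyzs) / length(xyzs)
  msd <- Reduce(`+`, lapply(xyzs, function(x) rowSums((x - mu)^2))) /
    length(xyzs)
  data.frame(chain = mats[[1L]]$chain, resnum = mats[[1L]]$resnum,
             rmsf = sqrt(msd))
}
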