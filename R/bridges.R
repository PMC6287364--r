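# Salt-bridge detection with the geometric criterion used throughout the
# design: a positively charged side-chain nitrogen (Lys NZ, Arg NH1/NH2, or
# doubly protonated His ND1/NE2) within 4.0 Angstrom (closed bound) of a
# carboxylate oxygen (Glu OE1/OE2, Asp OD1/OD2). Histidine counts as a donor
# only when its charge at the working pH is at least +0.5, i.e. when the HIP
# form dominates. Bridges are counted at residue-pair level: a bidentate
# Arg-Glu contact is one bridge, annotated with its minimum atom distance.

POS_BRIDGE_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2"),
                         HIS = c("ND1", "NE2"))
NEG_BRIDGE_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Salt-bridge criterion
#'
#' @param cutoff maximum N-O heavy-atom distance, Angstrom (closed bound,
#'   default 4.0).
#' @param ph working pH for histidine protonation gating (default 2.5).
#' @param his_requires_protonation only count His donors whose charge at
#'   `ph` is >= 0.5 (default TRUE).
#' @return list of class `bridge_criterion`.
#' @export
bridge_criterion <- function(cutoff = 4.0, ph = 2.5,
                             his_requires_protonation = TRUE) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, ph = ph,
                 his_requires_protonation = his_requires_protonation),
            class = "bridge_criterion")
}

# residue-level table of charged bridge atoms, with His protonation gating
bridge_atom_table <- function(structure, criterion, titration = NULL) {
  a <- structure$atoms[structure$atoms$is_protein, , drop = FALSE]
  pos <- a[(a$resname == "LYS" & a$name == "NZ") |
           (a$resname == "ARG" & a$name %in% c("NH1", "NH2")) |
           (a$resname == "HIS" & a$name %in% c("ND1", "NE2")), , drop = FALSE]
  neg <- a[(a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
           (a$resname == "ASP" & a$name %in% c("OD1", "OD2")), , drop = FALSE]
  if (criterion$his_requires_protonation && nrow(pos)) {
    his <- pos$resname == "HIS"
    if (any(his)) {
      if (!is.null(titration)) {
        st <- protonation_state(titration, criterion$ph)
        st <- st[st$site_kind == "HIS", , drop = FALSE]
        ok_key <- paste(st$chain, st$resnum, st$inscode)[st$charge >= 0.5]
      } else {
        # fall back to the solution pKa of histidine
        ok_key <- if (site_charge(hh_theta(criterion$ph, MODEL_PKA[["HIS"]]),
                                  FALSE) >= 0.5)
          unique(paste(pos$chain, pos$resnum, pos$inscode)[his]) else character()
      }
      keep <- !his | paste(pos$chain, pos$resnum, pos$inscode) %in% ok_key
      pos <- pos[keep, , drop = FALSE]
    }
  }
  list(pos = pos, neg = neg)
}

bridge_pairs_frame <- function(structure, criterion, titration = NULL) {
  tabs <- bridge_atom_table(structure, criterion, titration)
  pos <- tabs$pos; neg <- tabs$neg
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    return(data.frame())
  d <- sqrt(outer(pos$x, neg$x, "-")^2 + outer(pos$y, neg$y, "-")^2 +
            outer(pos$z, neg$z, "-")^2)
  hit <- which(d <= criterion$cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(data.frame())
  out <- data.frame(
    pos_chain = pos$chain[hit[, 1L]], pos_resnum = pos$resnum[hit[, 1L]],
    pos_inscode = pos$inscode[hit[, 1L]], pos_resname = pos$resname[hit[, 1L]],
    pos_atom = pos$name[hit[, 1L]],
    neg_chain = neg$chain[hit[, 2L]], neg_resnum = neg$resnum[hit[, 2L]],
    neg_inscode = neg$inscode[hit[, 2L]], neg_resname = neg$resname[hit[, 2L]],
    neg_atom = neg$name[hit[, 2L]],
    distance = d[hit], stringsAsFactors = FALSE)
  out
}

dedupe_residue_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  key <- paste(pairs$pos_chain, pairs$pos_resnum, pairs$pos_inscode,
               pairs$neg_chain, pairs$neg_resnum, pairs$neg_inscode)
  ord <- order(key, pairs$distance)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(key[ord]), , drop = FALSE]
  names(pairs)[names(pairs) == "distance"] <- "min_dist"
  pairs[order(pairs$pos_chain, pairs$pos_resnum, pairs$neg_chain,
              pairs$neg_resnum), , drop = FALSE]
}

#' Detect salt bridges in a single structure
#'
#' @param structure `pdb_structure`.
#' @param criterion [bridge_criterion()].
#' @param titration optional `titration_model` supplying histidine charges
#'   at `criterion$ph`; without it, the solution model pKa (6.3) gates His.
#' @return data.frame, one row per (positive residue, negative residue) pair
#'   within the cutoff, with the contributing atom pair of minimum distance,
#'   `min_dist` and `occupancy = 1`.
#' @export
detect_salt_bridges <- function(structure, criterion = bridge_criterion(),
                                titration = NULL) {
  out <- dedupe_residue_pairs(bridge_pairs_frame(structure, criterion,
                                                 titration))
  if (nrow(out)) out$occupancy <- 1
  rownames(out) <- NULL
  out
}

#' Salt-bridge persistence over an ensemble
#'
#' Evaluates the criterion in every frame and reports, per residue pair, the
#' fraction of frames in which it holds (occupancy) together with a summary
#' of the per-frame minimum distances.
#'
#' @param ensemble `pdb_ensemble`.
#' @param criterion [bridge_criterion()].
#' @param titration optional `titration_model` (from the reference frame).
#' @param occupancy_threshold keep pairs seen in at least this fraction of
#'   frames (default 0.5, majority persistence); 0 gives the union over
#'   frames.
#' @return data.frame with occupancy and mean/min/max of the per-frame
#'   minimum distance (over frames where the pair qualifies).
#' @export
bridge_occupancy <- function(ensemble, criterion = bridge_criterion(),
                             titration = NULL, occupancy_threshold = 0.5) {
  if (!is_ensemble(ensemble) || length(ensemble$frames) == 0L)
    stop("non-empty ensemble required")
  nf <- length(ensemble$frames)
  per_frame <- lapply(ensemble$frames, function(s)
    dedupe_residue_pairs(bridge_pairs_frame(s, criterion, titration)))
  all_hits <- do.call(rbind, per_frame[vapply(per_frame, nrow, 1L) > 0])
  if (is.null(all_hits) || nrow(all_hits) == 0L) return(data.frame())
  key <- paste(all_hits$pos_chain, all_hits$pos_resnum, all_hits$pos_inscode,
               all_hits$neg_chain, all_hits$neg_resnum, all_hits$neg_inscode)
  out <- do.call(rbind, lapply(split(all_hits, key), function(g) {
    r <- g[1L, c("pos_chain", "pos_resnum", "pos_inscode", "pos_resname",
                 "neg_chain", "neg_resnum", "neg_inscode", "neg_resname")]
    r$occupancy <- nrow(g) / nf
    r$mean_dist <- mean(g$min_dist)
    r$min_dist <- min(g$min_dist)
    r$max_dist <- max(g$min_dist)
    r
  }))
  out <- out[out$occupancy >= occupancy_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$pos_chain, out$pos_resnum, out$neg_chain, out$neg_resnum), ,
      drop = FALSE]
}
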