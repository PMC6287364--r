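# Candidate design: graft donor salt-bridge residue types onto incompatible
# acceptor positions, score each candidate with a pH-dependent folding
# free-energy difference, and classify with the +/-0.5 kcal/mol rule.
#
# The energy term is an openly documented stand-in with the pH-dependent
# structure of a proton-binding-isotherm integration: the mutant's Wyman
# term relative to the wild type, a fixed bonus per salt bridge gained (and
# penalty per bridge lost), and a steric penalty per clash introduced by the
# minimal side-chain grafting. Published per-variant free-energy values from
# comparable commercial engines are used only to test the classifier, never
# as regression targets for this term.

#' Design configuration
#'
#' @param target_ph pH at which stability is wanted (default 2.5).
#' @param reference_ph neutral reference pH for the Wyman integral.
#' @param bridge_bonus kcal/mol credited per net salt bridge gained.
#' @param clash_penalty kcal/mol charged per introduced steric clash.
#' @param clash_cutoff heavy-atom distance under which a grafted atom
#'   clashes, Angstrom.
#' @param titration [titration_config()] for the pKa model.
#' @param criterion [bridge_criterion()] for bridge detection.
#' @return named list.
#' @export
design_config <- function(target_ph = 2.5, reference_ph = 7.0,
                          bridge_bonus = 1.0, clash_penalty = 5.0,
                          clash_cutoff = 2.5,
                          titration = titration_config(target_ph = target_ph),
                          criterion = bridge_criterion(ph = target_ph)) {
  list(target_ph = target_ph, reference_ph = reference_ph,
       bridge_bonus = bridge_bonus, clash_penalty = clash_penalty,
       clash_cutoff = clash_cutoff, titration = titration,
       criterion = criterion)
}

#' Build a point-mutant structure by minimal side-chain grafting
#'
#' Renames the residue, truncates its side chain to CB, and for charged
#' residue types places the side-chain charged atoms along the CA->CB
#' direction at canonical distances (the same geometry the toy-structure
#' generator uses). The backbone is untouched. A grafted heavy atom closer
#' than `clash_cutoff` to any heavy atom of another residue raises the
#' clash count (attribute `clashes`).
#'
#' @param structure `pdb_structure`.
#' @param mutations data.frame with columns chain, resnum, wt, new (3-letter
#'   codes); wt must match the structure.
#' @param clash_cutoff Angstrom (default 2.5).
#' @return mutant `pdb_structure` with attribute `clashes` (integer).
#' @export
build_mutant <- function(structure, mutations, clash_cutoff = 2.5) {
  stopifnot(all(c("chain", "resnum", "wt", "new") %in% names(mutations)))
  a <- structure$atoms
  clashes <- 0L
  for (k in seq_len(nrow(mutations))) {
    mu <- mutations[k, ]
    sel <- a$chain == mu$chain & a$resnum == mu$resnum & a$inscode == ""
    if (!any(sel)) stop("no residue ", mu$chain, mu$resnum, " in structure")
    if (a$resname[sel][1L] != mu$wt)
      stop(sprintf("wild-type mismatch at %s%d: structure has %s, not %s",
                   mu$chain, mu$resnum, a$resname[sel][1L], mu$wt))
    if (!mu$new %in% names(AMINO3)) stop("unknown residue type ", mu$new)
    keep_names <- c("N", "CA", "C", "O", "CB", "OXT")
    drop <- sel & !(a$name %in% keep_names)
    a <- a[!drop, , drop = FALSE]
    sel <- a$chain == mu$chain & a$resnum == mu$resnum & a$inscode == ""
    a$resname[sel] <- mu$new
    geom <- CHARGED_ATOM_GEOM[[mu$new]]
    if (!is.null(geom)) {
      ca_row <- a[sel & a$name == "CA", , drop = FALSE]
      cb_row <- a[sel & a$name == "CB", , drop = FALSE]
      if (nrow(ca_row) == 0L) stop("residue ", mu$resnum, " lacks CA")
      ca <- as.numeric(ca_row[1L, c("x", "y", "z")])
      if (nrow(cb_row) >= 1L) {
        dir <- unit(as.numeric(cb_row[1L, c("x", "y", "z")]) - ca)
      } else {
        # pseudo-CB direction: away from the local backbone centroid
        bb <- a[sel & a$name %in% c("N", "C"), c("x", "y", "z"), drop = FALSE]
        dir <- unit(ca - colMeans(as.matrix(bb)))
      }
      new_rows <- do.call(rbind, lapply(seq_along(geom$atoms), function(m) {
        p <- ca + (geom$dist + 0.3 * (m - 1L)) * dir
        data.frame(serial = max(a$serial) + m, name = geom$atoms[m],
                   element = substr(geom$atoms[m], 1, 1), resname = mu$new,
                   chain = mu$chain, resnum = as.integer(mu$resnum),
                   inscode = "",
                   altloc = "", occupancy = 1,
                   x = p[1L], y = p[2L], z = p[3L], is_protein = TRUE,
                   stringsAsFactors = FALSE)
      }))
      other <- a[!(a$chain == mu$chain & a$resnum == mu$resnum &
                   a$inscode == ""), , drop = FALSE]
      for (m in seq_len(nrow(new_rows))) {
        d2 <- (other$x - new_rows$x[m])^2 + (other$y - new_rows$y[m])^2 +
              (other$z - new_rows$z[m])^2
        if (any(d2 < clash_cutoff^2)) clashes <- clashes + 1L
      }
      a <- rbind(a, new_rows)
    }
  }
  out <- new_structure(a, id = paste0(structure$id, "_mut"))
  attr(out, "clashes") <- clashes
  out
}

mutated_residues <- function(wt, mut) {
  rw <- residue_table(wt); rm_ <- residue_table(mut)
  if (nrow(rw) != nrow(rm_) ||
      !identical(paste(rw$chain, rw$resnum, rw$inscode),
                 paste(rm_$chain, rm_$resnum, rm_$inscode)))
    stop("wild type and mutant differ in residue topology")
  which(rw$resname != rm_$resname)
}

bridge_keys <- function(bridges) {
  if (nrow(bridges) == 0L) return(character())
  paste(bridges$pos_chain, bridges$pos_resnum, bridges$pos_inscode,
        bridges$neg_chain, bridges$neg_resnum, bridges$neg_inscode)
}

#' pH-dependent free-energy change of a mutation
#'
#' ddG_mut = [dG_unfold_wt(target pH) - dG_unfold_mut(target pH)] relative
#' to the reference pH (Wyman integration of the folded-minus-unfolded
#' proton-binding isotherms), minus `bridge_bonus` per net salt bridge the
#' mutation gains, plus `clash_penalty` per steric clash. Negative values
#' are stabilizing.
#'
#' @param wt,mutant `pdb_structure`s identical except at mutated residues.
#' @param config [design_config()].
#' @return list: `ddg` (kcal/mol), `titration_term`, `n_new_bridges`,
#'   `n_lost_bridges`, `n_clashes`.
#' @export
ddg_mutation <- function(wt, mutant, config = design_config()) {
  idx <- mutated_residues(wt, mutant)
  if (length(idx) == 0L)
    return(list(ddg = 0, titration_term = 0, n_new_bridges = 0L,
                n_lost_bridges = 0L, n_clashes = 0L))
  model_wt <- effective_pkas(wt, config$titration)
  model_mut <- effective_pkas(mutant, config$titration)
  d_wt <- ph_stability_delta(model_wt, NULL, config$reference_ph,
                             config$target_ph)
  d_mut <- ph_stability_delta(model_mut, NULL, config$reference_ph,
                              config$target_ph)
  titration_term <- d_wt - d_mut
  b_wt <- detect_salt_bridges(wt, config$criterion, model_wt)
  b_mut <- detect_salt_bridges(mutant, config$criterion, model_mut)
  k_wt <- bridge_keys(b_wt); k_mut <- bridge_keys(b_mut)
  n_new <- length(setdiff(k_mut, k_wt))
  n_lost <- length(setdiff(k_wt, k_mut))
  n_clash <- attr(mutant, "clashes")
  if (is.null(n_clash)) n_clash <- 0L
  ddg <- titration_term - config$bridge_bonus * (n_new - n_lost) +
    config$clash_penalty * n_clash
  list(ddg = ddg, titration_term = titration_term,
       n_new_bridges = n_new, n_lost_bridges = n_lost, n_clashes = n_clash)
}

#' Classify a mutation's free-energy change
#'
#' Below -0.5 kcal/mol: stabilizing; between -0.5 and +0.5 inclusive:
#' neutral; above +0.5: destabilizing.
#'
#' @param ddg numeric vector, kcal/mol.
#' @return character vector of labels.
#' @export
classify_effect <- function(ddg) {
  if (any(!is.finite(ddg))) stop("non-finite free-energy value")
  ifelse(ddg < -0.5, "stabilizing",
         ifelse(ddg > 0.5, "destabilizing", "neutral"))
}

#' Full homologous salt-bridge grafting pipeline
#'
#' Runs titration of the donor, surveys donor salt bridges (on a single
#' structure or an ensemble), aligns donor and acceptor chain sequences,
#' superposes the scaffolds on aligned C-alpha pairs, maps each donor bridge
#' onto the acceptor, and at every incompatible position grafts the donor
#' residue types (single or double mutation as required), scores the
#' candidate with [ddg_mutation()] and classifies it.
#'
#' @param donor `pdb_structure` of the bridge-donor scaffold.
#' @param acceptor `pdb_structure` of the design target.
#' @param config [design_config()].
#' @param donor_ensemble optional `pdb_ensemble`; when given, donor bridges
#'   come from [bridge_occupancy()] at `occupancy_threshold`.
#' @param occupancy_threshold persistence threshold for ensemble mode.
#' @return list of class `design_report`: alignment stats, superposition
#'   rmsd, donor bridge table, position calls, counts
#'   (conserved/incompatible/unmappable) and the candidate table
#'   (mutations, n_new_bridges, ddg_mut, effect).
#' @export
run_design_pipeline <- function(donor, acceptor, config = design_config(),
                                donor_ensemble = NULL,
                                occupancy_threshold = 0.5) {
  model_donor <- effective_pkas(donor, config$titration)
  donor_bridges <- if (is.null(donor_ensemble))
    detect_salt_bridges(donor, config$criterion, model_donor)
  else
    bridge_occupancy(donor_ensemble, config$criterion, model_donor,
                     occupancy_threshold)
  aln <- align_sequences(structure_sequence(donor),
                         structure_sequence(acceptor))
  dres <- residue_table(donor); ares <- residue_table(acceptor)
  dch <- dres$chain[1L]; ach <- ares$chain[1L]
  dca <- ca_coords(donor, dch); aca <- ca_coords(acceptor, ach)
  pm <- aln$position_map
  ok <- pm$a_index <= nrow(dca) & pm$b_index <= nrow(aca)
  sp <- superpose(dca[pm$a_index[ok], , drop = FALSE],
                  aca[pm$b_index[ok], , drop = FALSE])
  calls <- if (nrow(donor_bridges))
    map_bridge_positions(donor_bridges, aln, donor, acceptor, dch, ach)
  else
    data.frame()
  counts <- c(conserved = sum(calls$call == "conserved"),
              incompatible = sum(calls$call == "incompatible"),
              unmappable = sum(calls$call == "unmappable"))
  candidates <- list()
  inc <- which(calls$call == "incompatible")
  for (k in inc) {
    br <- donor_bridges[k, ]
    sides <- strsplit(calls$targets[k], ";")[[1L]]
    muts <- do.call(rbind, lapply(sides, function(side) {
      if (side == "pos")
        data.frame(chain = ach, resnum = calls$acc_pos_resnum[k],
                   wt = calls$acc_pos_resname[k], wt_new = br$pos_resname,
                   stringsAsFactors = FALSE)
      else
        data.frame(chain = ach, resnum = calls$acc_neg_resnum[k],
                   wt = calls$acc_neg_resname[k], wt_new = br$neg_resname,
                   stringsAsFactors = FALSE)
    }))
    names(muts)[names(muts) == "wt_new"] <- "new"
    label <- paste(sprintf("%s%d%s", AMINO3[muts$wt], muts$resnum,
                           AMINO3[muts$new]), collapse = "/")
    mutant <- tryCatch(
      build_mutant(acceptor, muts, config$clash_cutoff),
      error = function(e) e)
    if (inherits(mutant, "error")) {
      candidates[[length(candidates) + 1L]] <- data.frame(
        candidate = label, mutations = label, n_new_bridges = NA_integer_,
        ddg_mut = NA_real_, effect = paste("failed:",
                                           conditionMessage(mutant)),
        stringsAsFactors = FALSE)
      next
    }
    sc <- ddg_mutation(acceptor, mutant, config)
    candidates[[length(candidates) + 1L]] <- data.frame(
      candidate = label, mutations = label,
      n_new_bridges = sc$n_new_bridges, ddg_mut = sc$ddg,
      effect = classify_effect(sc$ddg), stringsAsFactors = FALSE)
  }
  cand <- if (length(candidates)) do.call(rbind, candidates) else
    data.frame(candidate = character(), mutations = character(),
               n_new_bridges = integer(), ddg_mut = numeric(),
               effect = character())
  cand <- cand[order(cand$ddg_mut), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(alignment = aln, superposition = sp,
                 donor_bridges = donor_bridges, calls = calls,
                 counts = counts, candidates = cand, config = config),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf(
    "<design_report: %d donor bridges; %d conserved, %d incompatible, %d unmappable; %d candidates>\n",
    nrow(x$donor_bridges), x$counts["conserved"], x$counts["incompatible"],
    x$counts["unmappable"], nrow(x$candidates)))
  invisible(x)
}
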