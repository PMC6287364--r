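# pH-dependent protonation: titratable-site discovery, a mean-field
# effective-pKa scheme, Henderson-Hasselbalch charges, proton-binding
# isotherms, and the Wyman integration that converts folded-minus-unfolded
# isotherms into a pH-dependent change of unfolding free energy.
#
# The pKa scheme is an openly documented mean-field model: a burial (Born)
# shift proportional to how many protein heavy atoms surround the site, plus
# screened Coulomb shifts from the other sites' partial charges, iterated to
# self-consistency. It shares the interface and the pH-integration structure
# of full continuum-electrostatics treatments without reproducing any
# particular solver.

MODEL_PKA <- c(ASP = 4.0, GLU = 4.4, HIS = 6.3, LYS = 10.4, ARG = 12.0,
               TYR = 9.6, CYS = 8.3, NTERM = 7.5, CTERM = 3.8)
ACID_SITE <- c(ASP = TRUE, GLU = TRUE, HIS = FALSE, LYS = FALSE, ARG = FALSE,
               TYR = TRUE, CYS = TRUE, NTERM = FALSE, CTERM = TRUE)
SITE_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  LYS = "NZ", ARG = c("NH1", "NH2"), TYR = "OH", CYS = "SG",
  NTERM = "N", CTERM = c("OXT", "O"))

KCAL_COULOMB <- 332       # kcal * Angstrom / mol / e^2
RGAS <- 1.9872041e-3      # kcal / mol / K

#' Default titration-model configuration
#'
#' @param epsilon_eff effective dielectric screening constant (> 1).
#' @param born_scale maximum burial-induced pKa shift (pKa units); acids are
#'   shifted up, bases down, in proportion to burial.
#' @param n_low,n_high heavy-atom neighbour counts (9 Angstrom sphere) mapped
#'   to burial 0 and 1.
#' @param temperature Kelvin.
#' @param target_ph pH at which self-consistent charges are evaluated.
#' @param tol convergence tolerance on the largest pKa change.
#' @param max_iter iteration cap for the mean-field cycle.
#' @return named list of constants.
#' @export
titration_config <- function(epsilon_eff = 20, born_scale = 1.5,
                             n_low = 15, n_high = 40,
                             temperature = 298.15, target_ph = 2.5,
                             tol = 0.01, max_iter = 50) {
  stopifnot(epsilon_eff > 1, tol > 0, n_high > n_low)
  list(epsilon_eff = epsilon_eff, born_scale = born_scale, n_low = n_low,
       n_high = n_high, temperature = temperature, target_ph = target_ph,
       tol = tol, max_iter = max_iter)
}

#' Find titratable sites in a structure
#'
#' One site per ASP/GLU/HIS/LYS/ARG/TYR residue, per free cysteine (CYS
#' pairs with SG-SG distance below 2.3 Angstrom are treated as disulfides
#' and excluded), plus the N- and C-terminus of every chain. Sites whose
#' residues carry none of the expected charged atoms are skipped with a
#' warning.
#'
#' @param structure `pdb_structure` with standard residue/atom names.
#' @return data.frame, one row per site: chain, resnum, inscode, resname,
#'   site_kind, model_pka, is_acid, cx/cy/cz (charged-atom centroid) and a
#'   list-column `atoms` with the charged atom names found.
#' @export
find_titratable_sites <- function(structure) {
  a <- structure$atoms[structure$atoms$is_protein, , drop = FALSE]
  res <- residue_table(structure)
  # disulfide detection
  free_cys <- rep(TRUE, nrow(res))
  cys_idx <- which(res$resname == "CYS")
  if (length(cys_idx) >= 2L) {
    sg <- lapply(cys_idx, function(i) {
      ra <- residue_atoms(structure, res$chain[i], res$resnum[i],
                          res$inscode[i])
      ra[ra$name == "SG", c("x", "y", "z")]
    })
    for (p in seq_along(cys_idx)) for (q in seq_along(cys_idx)) {
      if (p < q && nrow(sg[[p]]) && nrow(sg[[q]])) {
        d <- sqrt(sum((as.numeric(sg[[p]][1L, ]) -
                       as.numeric(sg[[q]][1L, ]))^2))
        if (d < 2.3) free_cys[cys_idx[c(p, q)]] <- FALSE
      }
    }
  }
  rows <- list()
  add_site <- function(kind, i) {
    ra <- residue_atoms(structure, res$chain[i], res$resnum[i], res$inscode[i])
    want <- SITE_ATOMS[[kind]]
    if (kind == "CTERM") want <- if ("OXT" %in% ra$name) "OXT" else "O"
    hit <- ra[ra$name %in% want, , drop = FALSE]
    if (nrow(hit) == 0L) {
      warning(sprintf("site %s %s%d has no charged atoms; skipped",
                      kind, res$chain[i], res$resnum[i]))
      return(NULL)
    }
    if (kind %in% c("ASP", "GLU", "HIS", "ARG") && nrow(hit) < 2L)
      warning(sprintf("site %s %s%d has only %d of its charged atoms",
                      kind, res$chain[i], res$resnum[i], nrow(hit)))
    data.frame(chain = res$chain[i], resnum = res$resnum[i],
               inscode = res$inscode[i], resname = res$resname[i],
               site_kind = kind, model_pka = MODEL_PKA[[kind]],
               is_acid = ACID_SITE[[kind]],
               cx = mean(hit$x), cy = mean(hit$y), cz = mean(hit$z),
               atoms = I(list(hit$name)), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(res))) {
    kind <- res$resname[i]
    if (kind %in% c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR") ||
        (kind == "CYS" && free_cys[i]))
      rows[[length(rows) + 1L]] <- add_site(kind, i)
  }
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    rows[[length(rows) + 1L]] <- add_site("NTERM", idx[1L])
    rows[[length(rows) + 1L]] <- add_site("CTERM", idx[length(idx)])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

hh_theta <- function(ph, pka) 1 / (1 + 10^(ph - pka))

site_charge <- function(theta, is_acid) ifelse(is_acid, -(1 - theta), theta)

#' Self-consistent effective pKas
#'
#' Mean-field scheme: (1) burial b of each site from the heavy-atom
#' neighbour count around its charged-atom centroid, clamped linearly
#' between `n_low` and `n_high`; (2) a Born-type desolvation shift
#' +born_scale * b for acids and -born_scale * b for bases; (3) pairwise
#' screened-Coulomb shifts -sum_j q_j * 332 / (eps * r_ij) / (ln10 * R * T)
#' with the partner charges q_j evaluated at the target pH from the current
#' effective pKas; iterate to self-consistency.
#'
#' @param structure `pdb_structure`.
#' @param config from [titration_config()].
#' @param sites optional precomputed site table.
#' @return `titration_model`: the site table with `effective_pka`, plus the
#'   config, convergence flag and iteration count.
#' @export
effective_pkas <- function(structure, config = titration_config(),
                           sites = NULL) {
  if (is.null(sites)) sites <- find_titratable_sites(structure)
  if (is.null(sites) || nrow(sites) == 0L) {
    empty <- data.frame(chain = character(), resnum = integer(),
                        inscode = character(), resname = character(),
                        site_kind = character(), model_pka = numeric(),
                        is_acid = logical(), cx = numeric(), cy = numeric(),
                        cz = numeric(), burial = numeric(),
                        effective_pka = numeric())
    return(structure(list(sites = empty, config = config, converged = TRUE,
                          iterations = 0L), class = "titration_model"))
  }
  n <- nrow(sites)
  burial <- vapply(seq_len(n), function(i) {
    cnt <- neighbor_count(structure, c(sites$cx[i], sites$cy[i], sites$cz[i]),
                          radius = 9)
    min(max((cnt - config$n_low) / (config$n_high - config$n_low), 0), 1)
  }, numeric(1L))
  born <- ifelse(sites$is_acid, 1, -1) * config$born_scale * burial
  cen <- cbind(sites$cx, sites$cy, sites$cz)
  rr <- as.matrix(stats::dist(cen))
  rr[rr < 1e-3] <- 1e-3   # guard against coincident centroids
  lnRT <- log(10) * RGAS * config$temperature
  pka <- sites$model_pka + born
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    q <- site_charge(hh_theta(config$target_ph, pka), sites$is_acid)
    shift <- vapply(seq_len(n), function(i) {
      if (n == 1L) return(0)
      j <- setdiff(seq_len(n), i)
      -sum(q[j] * KCAL_COULOMB / (config$epsilon_eff * rr[i, j])) / lnRT
    }, numeric(1L))
    new_pka <- sites$model_pka + born + shift
    if (max(abs(new_pka - pka)) < config$tol) {
      pka <- new_pka
      converged <- TRUE
      break
    }
    pka <- new_pka
  }
  sites$burial <- burial
  sites$effective_pka <- pka
  structure(list(sites = sites, config = config, converged = converged,
                 iterations = iter), class = "titration_model")
}

#' Titration model from model pKas only (unfolded-state reference)
#'
#' The unfolded (null) reference uses solution model pKas with no
#' environmental shifts, the standard convention for pH-stability work.
#'
#' @param model a `titration_model` (its shifts are discarded).
#' @return `titration_model` with effective_pka = model_pka.
#' @export
unfolded_reference <- function(model) {
  model$sites$effective_pka <- model$sites$model_pka
  model$sites$burial <- rep(0, nrow(model$sites))
  model$converged <- TRUE
  model
}

#' Per-site protonation fractions and charges at a pH
#'
#' theta = 1 / (1 + 10^(pH - pKa_eff)); acid charge -(1 - theta), base
#' charge +theta.
#'
#' @param model `titration_model`.
#' @param ph pH value.
#' @return site table with `theta` and `charge` columns.
#' @export
protonation_state <- function(model, ph) {
  s <- model$sites
  s$theta <- hh_theta(ph, s$effective_pka)
  s$charge <- site_charge(s$theta, s$is_acid)
  s
}

#' Net-charge (proton-binding) curve over a pH grid
#'
#' @param model `titration_model`.
#' @param ph_grid increasing pH values.
#' @return data.frame (ph, q); q is monotone non-increasing.
#' @export
net_charge_curve <- function(model, ph_grid) {
  stopifnot(!is.unsorted(ph_grid))
  q <- vapply(ph_grid, function(p) sum(protonation_state(model, p)$charge),
              numeric(1L))
  data.frame(ph = ph_grid, q = q)
}

#' pH dependence of unfolding free energy (Wyman integration)
#'
#' DeltaG_unfold(ph_to) - DeltaG_unfold(ph_from) =
#'   -R T ln10 * integral over pH of [Q_unfolded - Q_folded] dpH,
#' evaluated with composite Simpson quadrature on a grid of step <= 0.01 pH
#' units. Antisymmetric under swapping the limits.
#'
#' @param folded_model `titration_model` of the folded protein.
#' @param unfolded_model matching model with unshifted (model) pKas; built
#'   with [unfolded_reference()] if omitted.
#' @param ph_from,ph_to integration limits.
#' @return change in unfolding free energy, kcal/mol.
#' @export
ph_stability_delta <- function(folded_model, unfolded_model = NULL,
                               ph_from, ph_to) {
  if (is.null(unfolded_model)) unfolded_model <- unfolded_reference(folded_model)
  stopifnot(identical(folded_model$sites$site_kind,
                      unfolded_model$sites$site_kind))
  if (ph_from == ph_to) return(0)
  sgn <- if (ph_to >= ph_from) 1 else -1
  lo <- min(ph_from, ph_to); hi <- max(ph_from, ph_to)
  n <- max(2L, ceiling((hi - lo) / 0.01))
  if (n %% 2L == 1L) n <- n + 1L                      # Simpson needs even n
  grid <- seq(lo, hi, length.out = n + 1L)
  dq <- net_charge_curve(unfolded_model, grid)$q -
        net_charge_curve(folded_model, grid)$q
  h <- (hi - lo) / n
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  integral <- h / 3 * sum(w * dq)
  rt <- RGAS * folded_model$config$temperature
  sgn * (-rt * log(10) * integral)
}
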