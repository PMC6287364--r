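# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain double loops, a quaternion (Horn)
# superposition, closed-form titration integrals.

# Exhaustive all-pairs salt-bridge scan: loops over every atom pair and
# applies the charged-atom criterion literally. Returns a sorted character
# set of "poschain:posres|negchain:negres" keys.
oracle_bridge_keys <- function(structure, cutoff = 4.0, ph = 2.5,
                               his_gate = TRUE) {
  a <- structure$atoms[structure$atoms$is_protein, , drop = FALSE]
  his_charged <- (1 / (1 + 10^(ph - 6.3))) >= 0.5
  keys <- character()
  for (i in seq_len(nrow(a))) {
    pos_ok <- (a$resname[i] == "LYS" && a$name[i] == "NZ") ||
      (a$resname[i] == "ARG" && a$name[i] %in% c("NH1", "NH2")) ||
      (a$resname[i] == "HIS" && a$name[i] %in% c("ND1", "NE2") &&
         (!his_gate || his_charged))
    if (!pos_ok) next
    for (j in seq_len(nrow(a))) {
      neg_ok <- (a$resname[j] == "GLU" && a$name[j] %in% c("OE1", "OE2")) ||
        (a$resname[j] == "ASP" && a$name[j] %in% c("OD1", "OD2"))
      if (!neg_ok) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= cutoff)
        keys <- c(keys, paste0(a$chain[i], ":", a$resnum[i], "|",
                               a$chain[j], ":", a$resnum[j]))
    }
  }
  sort(unique(keys))
}

bridge_keys_of <- function(bridges) {
  if (nrow(bridges) == 0L) return(character())
  sort(paste0(bridges$pos_chain, ":", bridges$pos_resnum, "|",
              bridges$neg_chain, ":", bridges$neg_resnum))
}

# Horn's quaternion method for least-squares rigid superposition; returns
# the rmsd of b fitted onto a.
oracle_quaternion_rmsd <- function(x_a, x_b) {
  ca <- colMeans(x_a); cb <- colMeans(x_b)
  A <- sweep(x_a, 2, ca); B <- sweep(x_b, 2, cb)
  S <- t(B) %*% A
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  eig <- eigen(K, symmetric = TRUE)
  q <- eig$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fit <- B %*% t(R)
  sqrt(mean(rowSums((fit - A)^2)))
}

# Closed-form Wyman integral for a single acid site: the indefinite
# integral of the deprotonated fraction is F(pH) = log10(1 + 10^(pH-pKa)).
oracle_one_acid_delta <- function(pka_f, pka_u, ph_from, ph_to,
                                  temperature = 298.15) {
  Fof <- function(ph, pka) log10(1 + 10^(ph - pka))
  int_qu_minus_qf <-
    (Fof(ph_to, pka_f) - Fof(ph_from, pka_f)) -
    (Fof(ph_to, pka_u) - Fof(ph_from, pka_u))
  -1.9872041e-3 * temperature * log(10) * int_qu_minus_qf
}

# Minimal hand-built structure: one row per atom with defaults filled in.
flat_structure <- function(df, id = "flat") {
  defaults <- data.frame(serial = seq_len(nrow(df)), element = "X",
                         inscode = "", altloc = "", occupancy = 1,
                         chain = "A", is_protein = TRUE,
                         stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$element <- substr(df$name, 1, 1)
  new_structure(df[, c("serial", "name", "element", "resname", "chain",
                       "resnum", "inscode", "altloc", "occupancy",
                       "x", "y", "z", "is_protein")], id = id)
}

# A hand-made one-site titration model (folded pKa set directly).
one_site_model <- function(site_kind, model_pka, effective_pka,
                           is_acid, config = titration_config()) {
  sites <- data.frame(chain = "A", resnum = 1L, inscode = "",
                      resname = site_kind, site_kind = site_kind,
                      model_pka = model_pka, is_acid = is_acid,
                      cx = 0, cy = 0, cz = 0, burial = 0,
                      effective_pka = effective_pka)
  structure(list(sites = sites, config = config, converged = TRUE,
                 iterations = 1L), class = "titration_model")
}

# Two facing residues whose CA->CB axes point at each other, so grafted
# charged side chains meet in the middle; `sep` is the CA-CA distance.
facing_pair_structure <- function(res1 = "ALA", res2 = "ALA", sep = 11.5,
                                  extra = NULL) {
  df <- data.frame(
    name = rep(c("CA", "CB"), 2),
    resname = rep(c(res1, res2), each = 2),
    resnum = rep(c(1L, 2L), each = 2),
    x = c(0, 1.53, sep, sep - 1.53), y = 0, z = 0,
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  flat_structure(df)
}
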