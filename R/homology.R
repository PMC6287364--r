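# Homology layer: global affine-gap sequence alignment, rigid-body (Kabsch)
# superposition, and projection of donor salt-bridge positions onto an
# acceptor structure through the alignment.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 substitution scores (standard half-bit matrix, 20 amino acids)
BLOSUM62 <- local({
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4)
  m <- matrix(v, 20, 20, byrow = TRUE, dimnames = list(AA1, AA1))
  m
})

#' Global affine-gap pairwise alignment (Needleman-Wunsch / Gotoh)
#'
#' True global alignment with affine gap costs and end gaps penalized; a gap
#' of length L costs gap_open + L * gap_extend. Identity and similarity use
#' all alignment columns, including gap columns, as the denominator
#' (EMBOSS-needle convention), so the percentages are convention-sensitive.
#'
#' @param seq_a,seq_b amino-acid strings (one-letter codes).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return list of class `alignment_result`: `aligned_a`, `aligned_b` (equal
#'   length, "-" for gaps), `score`, `identity`, `similarity` (percent),
#'   and `position_map`, a data.frame of 1-based residue indices
#'   (a_index, b_index) for columns with both residues present.
#' @export
align_sequences <- function(seq_a, seq_b, matrix = BLOSUM62,
                            gap_open = 10, gap_extend = 0.5) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) == 0L || length(b) == 0L) stop("empty sequence")
  bad <- setdiff(c(a, b), rownames(matrix))
  if (length(bad)) stop("invalid residue letters: ", paste(bad, collapse = ""))
  n <- length(a); m <- length(b)
  NEG <- -1e9
  go <- gap_open + gap_extend; ge <- gap_extend
  M <- matrix(NEG, n + 1L, m + 1L)   # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -(gap_open + ge * (i - 1L))
  for (j in 2L:(m + 1L)) Y[1L, j] <- -(gap_open + ge * (j - 1L))
  sub <- matrix[a, b, drop = FALSE]
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- sub[i - 1L, j - 1L]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - go, X[i - 1L, j] - ge,
                     Y[i - 1L, j] - go)
      Y[i, j] <- max(M[i, j - 1L] - go, Y[i, j - 1L] - ge,
                     X[i, j - 1L] - go)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  i <- n + 1L; j <- m + 1L
  al_a <- character(); al_b <- character()
  tol <- 1e-9
  while (i > 1L || j > 1L) {
    if (state == 1L) {            # M
      s <- sub[i - 1L, j - 1L]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which(abs(prev + s - M[i, j]) < tol)[1L]
      al_a <- c(a[i - 1L], al_a); al_b <- c(b[j - 1L], al_b)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {     # X: gap in b
      if (i == 1L) { state <- 3L; next }
      cand <- c(M[i - 1L, j] - go, X[i - 1L, j] - ge, Y[i - 1L, j] - go)
      nxt <- which(abs(cand - X[i, j]) < tol)[1L]
      al_a <- c(a[i - 1L], al_a); al_b <- c("-", al_b)
      i <- i - 1L
      state <- nxt
    } else {                      # Y: gap in a
      if (j == 1L) { state <- 2L; next }
      cand <- c(M[i, j - 1L] - go, Y[i, j - 1L] - ge, X[i, j - 1L] - go)
      nxt <- which(abs(cand - Y[i, j]) < tol)[1L]
      al_a <- c("-", al_a); al_b <- c(b[j - 1L], al_b)
      j <- j - 1L
      state <- nxt
    }
  }
  cols <- length(al_a)
  both <- al_a != "-" & al_b != "-"
  ident <- sum(both & al_a == al_b)
  simil <- sum(vapply(which(both), function(k)
    matrix[al_a[k], al_b[k]] > 0, logical(1L)))
  pm <- data.frame(a_index = cumsum(al_a != "-")[both],
                   b_index = cumsum(al_b != "-")[both])
  structure(list(aligned_a = paste(al_a, collapse = ""),
                 aligned_b = paste(al_b, collapse = ""),
                 score = score,
                 identity = 100 * ident / cols,
                 similarity = 100 * simil / cols,
                 position_map = pm),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: score %.1f, identity %.2f%%, similarity %.2f%%>\n",
              x$score, x$identity, x$similarity))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' R %*% x_b + t onto x_a over paired points; reflections are corrected so
#' det(R) = +1.
#'
#' @param x_a,x_b N x 3 coordinate matrices of paired points (N >= 3,
#'   non-collinear), e.g. matched C-alpha atoms.
#' @return list of class `superposition`: `rotation` (3x3), `translation`,
#'   `rmsd` (Angstrom, over the pairs), `n_pairs`.
#' @export
superpose <- function(x_a, x_b) {
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  stopifnot(ncol(x_a) == 3L, ncol(x_b) == 3L, nrow(x_a) == nrow(x_b))
  n <- nrow(x_a)
  if (n < 3L) stop("need at least 3 point pairs")
  ca <- colMeans(x_a); cb <- colMeans(x_b)
  A <- sweep(x_a, 2L, ca); B <- sweep(x_b, 2L, cb)
  if (min(svd(A)$d) < 1e-10 * max(svd(A)$d))
    stop("collinear (degenerate) point set")
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ca - as.vector(R %*% cb)
  fit <- sweep(B %*% t(R), 2L, ca, "+") + 0  # rotated B back in a's frame
  rmsd <- sqrt(mean(rowSums((fit - x_a)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_pairs = n), class = "superposition")
}

#' C-alpha coordinates of a chain
#'
#' @param structure `pdb_structure`.
#' @param chain chain id (default first).
#' @return matrix, one row per residue with a CA atom, rownames = resnum.
#' @export
ca_coords <- function(structure, chain = NULL) {
  a <- structure$atoms[structure$atoms$is_protein, , drop = FALSE]
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain & a$name == "CA", , drop = FALSE]
  out <- as.matrix(a[, c("x", "y", "z")])
  rownames(out) <- a$resnum
  out
}

#' Apply a superposition to a structure
#'
#' @param structure `pdb_structure`.
#' @param sp `superposition` (moves the structure into the reference frame).
#' @return transformed `pdb_structure`.
#' @export
transform_structure <- function(structure, sp) {
  xyz <- coords(structure) %*% t(sp$rotation)
  xyz <- sweep(xyz, 2L, sp$translation, "+")
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

#' Map donor salt bridges onto acceptor positions
#'
#' For each donor bridge, finds the acceptor residues at the
#' alignment-mapped positions and calls the pair `conserved` when the
#' acceptor already has one positive-type (ARG/LYS/HIS) and one
#' negative-type (ASP/GLU) residue there, `incompatible` otherwise (with the
#' offending side(s) recorded as mutation targets), or `unmappable` when
#' either position falls in a gap column.
#'
#' @param donor_bridges data.frame from [detect_salt_bridges()] or
#'   [bridge_occupancy()] on the donor.
#' @param alignment `alignment_result` of donor (a) vs acceptor (b) chain
#'   sequences.
#' @param donor,acceptor the two `pdb_structure`s.
#' @param donor_chain,acceptor_chain chain ids (default first chain).
#' @return data.frame, one row per donor bridge: donor residue labels,
#'   mapped acceptor positions/residues, `call`
#'   (conserved/incompatible/unmappable) and `targets` (";"-separated sides
#'   needing mutation: "pos", "neg").
#' @export
map_bridge_positions <- function(donor_bridges, alignment, donor, acceptor,
                                 donor_chain = NULL, acceptor_chain = NULL) {
  dres <- residue_table(donor)
  if (is.null(donor_chain)) donor_chain <- dres$chain[1L]
  dres <- dres[dres$chain == donor_chain, , drop = FALSE]
  ares <- residue_table(acceptor)
  if (is.null(acceptor_chain)) acceptor_chain <- ares$chain[1L]
  ares <- ares[ares$chain == acceptor_chain, , drop = FALSE]
  pm <- alignment$position_map
  map_one <- function(resnum, inscode) {
    di <- which(dres$resnum == resnum & dres$inscode == inscode)
    if (length(di) != 1L) return(NA_integer_)
    hit <- pm$b_index[pm$a_index == di]
    if (length(hit) != 1L) return(NA_integer_)
    hit
  }
  rows <- lapply(seq_len(nrow(donor_bridges)), function(k) {
    br <- donor_bridges[k, ]
    ai_pos <- map_one(br$pos_resnum, br$pos_inscode)
    ai_neg <- map_one(br$neg_resnum, br$neg_inscode)
    out <- data.frame(
      donor_pos = sprintf("%s%d", br$pos_resname, br$pos_resnum),
      donor_neg = sprintf("%s%d", br$neg_resname, br$neg_resnum),
      acc_pos_resnum = NA_integer_, acc_pos_resname = NA_character_,
      acc_neg_resnum = NA_integer_, acc_neg_resname = NA_character_,
      call = "unmappable", targets = "", stringsAsFactors = FALSE)
    if (is.na(ai_pos) || is.na(ai_neg)) return(out)
    out$acc_pos_resnum <- ares$resnum[ai_pos]
    out$acc_pos_resname <- ares$resname[ai_pos]
    out$acc_neg_resnum <- ares$resnum[ai_neg]
    out$acc_neg_resname <- ares$resname[ai_neg]
    pos_ok <- out$acc_pos_resname %in% c("ARG", "LYS", "HIS")
    neg_ok <- out$acc_neg_resname %in% c("ASP", "GLU")
    if (pos_ok && neg_ok) {
      out$call <- "conserved"
    } else {
      out$call <- "incompatible"
      out$targets <- paste(c(if (!pos_ok) "pos", if (!neg_ok) "neg"),
                           collapse = ";")
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
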