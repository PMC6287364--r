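fixture_pdb_text <- function(models = 1L) {
  # 2 residues x 8 atoms, hand-written fixed-width records
  atoms <- c(
    "ATOM      1  N   ARG A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ARG A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ARG A   1      12.543   7.243  -4.810  1.00  0.00           C",
    "ATOM      4  O   ARG A   1      13.066   7.321  -3.697  1.00  0.00           O",
    "ATOM      5  CB  ARG A   1      10.521   5.996  -4.102  1.00  0.00           C",
    "ATOM      6  NH1 ARG A   1       8.424   5.960  -1.173  1.00  0.00           N",
    "ATOM      7  NH2 ARG A   1       9.916   5.832  -0.532  1.00  0.00           N",
    "ATOM      8  NE  ARG A   1       9.101   6.023  -2.428  1.00  0.00           N",
    "ATOM      9  N   GLU A   2      12.732   8.170  -5.753  1.00  0.00           N",
    "ATOM     10  CA  GLU A   2      13.563   9.352  -5.531  1.00  0.00           C",
    "ATOM     11  C   GLU A   2      14.993   8.970  -5.148  1.00  0.00           C",
    "ATOM     12  O   GLU A   2      15.661   9.702  -4.415  1.00  0.00           O",
    "ATOM     13  CB  GLU A   2      13.591  10.215  -6.796  1.00  0.00           C",
    "ATOM     14  CD  GLU A   2      13.350  12.571  -7.466  1.00  0.00           C",
    "ATOM     15  OE1 GLU A   2      12.255  12.417  -8.048  1.00  0.00           O",
    "ATOM     16  OE2 GLU A   2      14.006  13.661  -7.491  1.00  0.00           O")
  if (models == 1L) return(c(atoms, "END"))
  out <- character()
  for (m in seq_len(models))
    out <- c(out, sprintf("MODEL     %4d", m), atoms, "ENDMDL")
  c(out, "END")
}

test_that("single-model PDB reads as a structure with all heavy atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_text(1L), f)
  s <- read_pdb(f)
  expect_s3_class(s, "pdb_structure")
  expect_equal(nrow(s$atoms), 16L)
  expect_equal(nrow(residue_table(s)), 2L)
  expect_equal(structure_sequence(s), "RE")
})

test_that("MODEL blocks read as an ensemble of matching frames", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_text(3L), f)
  e <- read_pdb(f)
  expect_s3_class(e, "pdb_ensemble")
  expect_length(e, 3L)
  expect_equal(nrow(e$frames[[2L]]$atoms), 16L)
})

test_that("keep-first altloc policy keeps one highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ARG A  55      10.000   1.000   1.000  1.00  0.00           C",
    "ATOM      2  NH1AARG A  55      12.000   1.000   1.000  0.50  0.00           N",
    "ATOM      3  NH1BARG A  55      12.500   1.500   1.000  0.50  0.00           N",
    "END")
  writeLines(lines, f)
  s <- read_pdb(f, altloc_policy = "keep-first")
  expect_equal(sum(s$atoms$name == "NH1"), 1L)
  # 0.5/0.5 tie broken by altloc letter: state A kept
  expect_equal(s$atoms$x[s$atoms$name == "NH1"], 12.0)
  s_all <- read_pdb(f, altloc_policy = "keep-all")
  expect_equal(sum(s_all$atoms$name == "NH1"), 2L)
})

test_that("write/read round-trip preserves names, numbering and coords", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_text(1L), f)
  s <- read_pdb(f)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f2)
  s2 <- read_pdb(f2)
  expect_identical(s2$atoms$name, s$atoms$name)
  expect_identical(s2$atoms$resnum, s$atoms$resnum)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # ensemble round-trip keeps the frame count
  e <- new_ensemble(list(s, s, s))
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(e, f3)
  expect_length(read_pdb(f3), 3L)
})

test_that("degenerate inputs give distinct errors", {
  expect_error(read_pdb(tempfile()), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_pdb(f))
  s <- make_toy_structure(n_residues = 4)
  s$atoms$x[1] <- 12345.0
  expect_error(write_pdb(s, tempfile()), "fixed-width")
  expect_error(new_structure(s$atoms[0, ]), "at least one atom")
})

test_that("neighbor_count matches a brute-force scan", {
  one <- flat_structure(data.frame(name = "CA", resname = "ALA", resnum = 1L,
                                   x = 5, y = 0, z = 0))
  expect_equal(neighbor_count(one, c(0, 0, 0), 9), 1L)
  expect_equal(neighbor_count(one, c(0, 0, 0), 4), 0L)
  grid <- expand.grid(x = seq(0, 9, by = 3), y = seq(0, 9, by = 3), z = 0)
  gs <- flat_structure(data.frame(name = "CA", resname = "ALA",
                                  resnum = seq_len(nrow(grid)),
                                  x = grid$x, y = grid$y, z = grid$z))
  brute <- sum(sqrt(grid$x^2 + grid$y^2) <= 9 & (grid$x + grid$y) > 0)
  expect_equal(neighbor_count(gs, c(0, 0, 0), 9), brute)
  # random point clouds vs an independent O(N) scan
  set.seed(42)
  for (k in 1:20) {
    pts <- matrix(runif(60, -10, 10), ncol = 3)
    st <- flat_structure(data.frame(name = "CA", resname = "ALA",
                                    resnum = 1:20, x = pts[, 1],
                                    y = pts[, 2], z = pts[, 3]))
    ctr <- runif(3, -10, 10)
    d <- sqrt(colSums((t(pts) - ctr)^2))
    expect_equal(neighbor_count(st, ctr, 6), sum(d <= 6 & d > 0))
  }
})

test_that("crystal packing reproduces the Matthews relation", {
  # right-angle cell: volume is exactly a*b*c
  cp <- crystal_packing(10, 10, 10, z = 1, protein_mass = 500)
  expect_equal(cp$volume, 1000)
  expect_equal(cp$vm, 2.0)
  # boundary: vm = 1.66 * vbar gives zero solvent
  expect_equal(matthews_solvent_fraction(1.66 * 0.74, 0.74), 0)
  # monoclinic cell volume = a b c sin(beta)
  cpm <- crystal_packing(41.2, 99.6, 48.3, beta = 113.9, z = 2,
                         protein_mass = 37000)
  expect_equal(cpm$volume, 41.2 * 99.6 * 48.3 * sin(113.9 * pi / 180))
  expect_error(crystal_packing(10, 10, 10, z = 1, protein_mass = -5))
})
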