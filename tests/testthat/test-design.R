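test_that("build_mutant edits identity, grafts charged atoms, flags clashes", {
  s <- make_toy_structure(n_residues = 60)
  mut <- build_mutant(s, data.frame(chain = "A", resnum = 55, wt = "ALA",
                                    new = "ARG"))
  ra <- mut$atoms[mut$atoms$resnum == 55, ]
  expect_true(all(ra$resname == "ARG"))
  expect_true(all(c("NH1", "NH2") %in% ra$name))
  expect_equal(attr(mut, "clashes"), 0L)
  # backbone untouched
  expect_equal(mut$atoms[mut$atoms$name == "CA", c("x", "y", "z")],
               s$atoms[s$atoms$name == "CA", c("x", "y", "z")],
               ignore_attr = TRUE)
  expect_error(build_mutant(s, data.frame(chain = "A", resnum = 3,
                                          wt = "GLY", new = "ARG")),
               "mismatch")
  expect_error(build_mutant(s, data.frame(chain = "A", resnum = 999,
                                          wt = "ALA", new = "ARG")),
               "no residue")
  # a wall of atoms in front of the grafted side chain raises the clash flag
  wall <- facing_pair_structure(sep = 30, extra = data.frame(
    name = "CB", resname = "ALA", resnum = 3L,
    x = 4.3, y = 0.5, z = 0, stringsAsFactors = FALSE))
  mw <- build_mutant(wall, data.frame(chain = "A", resnum = 1, wt = "ALA",
                                      new = "ARG"))
  expect_gt(attr(mw, "clashes"), 0L)
})

test_that("a grafted double mutant forms the designed bridge when geometry permits", {
  s <- facing_pair_structure(sep = 11.5)
  expect_equal(nrow(detect_salt_bridges(s)), 0L)
  mut <- build_mutant(s, data.frame(chain = "A", resnum = c(1, 2),
                                    wt = "ALA", new = c("ARG", "GLU")))
  b <- detect_salt_bridges(mut)
  expect_equal(nrow(b), 1L)
  expect_identical(bridge_keys_of(b), oracle_bridge_keys(mut))
  expect_equal(attr(mut, "clashes"), 0L)
})

test_that("ddg is zero for a null mutation and composes its terms", {
  s <- make_toy_structure(n_residues = 30)
  expect_identical(ddg_mutation(s, s)$ddg, 0)
  # clash-only case: +clash_penalty exactly (no titratable sites besides the
  # grafted one, which is isolated in both folded and unfolded states)
  wall_atoms <- data.frame(name = "CB", resname = "ALA", resnum = 3:4,
                           x = c(4.5, 5.0), y = c(0.8, -0.8), z = 0,
                           stringsAsFactors = FALSE)
  wt <- facing_pair_structure(sep = 30, extra = wall_atoms)
  mut <- build_mutant(wt, data.frame(chain = "A", resnum = 1, wt = "ALA",
                                     new = "LYS"))
  expect_gt(attr(mut, "clashes"), 0L)
  sc <- suppressWarnings(ddg_mutation(wt, mut))
  expect_equal(sc$titration_term, 0)
  expect_equal(sc$ddg, 5.0 * sc$n_clashes)
  # bridge-forming mutation: titration term (vs independent closed form)
  # minus one bridge bonus
  pair <- facing_pair_structure(sep = 11.5)
  mu2 <- build_mutant(pair, data.frame(chain = "A", resnum = c(1, 2),
                                       wt = "ALA", new = c("ARG", "GLU")))
  sc2 <- suppressWarnings(ddg_mutation(pair, mu2))
  expect_equal(sc2$n_new_bridges, 1L)
  expect_equal(sc2$n_clashes, 0L)
  # independent oracle for the titration term: adaptive quadrature over the
  # mutant's folded-minus-unfolded isotherm difference (the wild type here
  # has no titratable sites, so its Wyman term vanishes)
  m_mut <- suppressWarnings(effective_pkas(mu2))
  qdiff <- function(ph) {
    vapply(ph, function(p) {
      th_f <- 1 / (1 + 10^(p - m_mut$sites$effective_pka))
      th_u <- 1 / (1 + 10^(p - m_mut$sites$model_pka))
      qf <- ifelse(m_mut$sites$is_acid, -(1 - th_f), th_f)
      qu <- ifelse(m_mut$sites$is_acid, -(1 - th_u), th_u)
      sum(qu) - sum(qf)
    }, numeric(1))
  }
  rtln10 <- 1.9872041e-3 * 298.15 * log(10)
  d_mut_oracle <- -rtln10 * stats::integrate(qdiff, 7, 2.5,
                                             rel.tol = 1e-10)$value
  expect_equal(sc2$titration_term, -d_mut_oracle, tolerance = 1e-6)
  expect_equal(sc2$ddg, sc2$titration_term - 1.0, tolerance = 1e-12)
  expect_lt(sc2$ddg, 0)
  # structures differing outside mutated sites are rejected
  other <- make_toy_structure(n_residues = 31)
  expect_error(ddg_mutation(make_toy_structure(n_residues = 30), other),
               "topology")
})

test_that("the +/-0.5 kcal/mol rule partitions the line correctly", {
  expect_equal(classify_effect(-3.58), "stabilizing")
  expect_equal(classify_effect(0.22), "neutral")
  expect_equal(classify_effect(0.95), "destabilizing")
  expect_equal(classify_effect(-0.5), "neutral")
  expect_equal(classify_effect(0.5), "neutral")
  expect_error(classify_effect(NaN), "non-finite")
  # exactly one label for any finite value
  set.seed(2)
  x <- runif(200, -6, 6)
  lab <- classify_effect(x)
  expect_true(all(lab %in% c("stabilizing", "neutral", "destabilizing")))
  expect_identical(lab == "stabilizing", x < -0.5)
  expect_identical(lab == "destabilizing", x > 0.5)
})

test_that("self-design yields all-conserved bridges and no candidates", {
  donor <- make_toy_structure(n_residues = 30, planted_pairs = data.frame(
    basic = "ARG", acidic = "GLU", distance = 3.5))
  rep <- run_design_pipeline(donor, donor)
  expect_equal(unname(rep$counts["conserved"]), nrow(rep$donor_bridges))
  expect_equal(unname(rep$counts["incompatible"]), 0L)
  expect_equal(nrow(rep$candidates), 0L)
  expect_lt(rep$superposition$rmsd, 1e-9)
})

test_that("pipeline reports planted conserved/incompatible counts and is consistent", {
  donor <- make_toy_structure(n_residues = 40, planted_pairs = data.frame(
    basic = c("ARG", "LYS", "ARG"), acidic = c("GLU", "ASP", "GLU"),
    distance = c(3.5, 3.2, 3.8)))
  acceptor <- make_toy_structure(n_residues = 40, planted_pairs = data.frame(
    basic = "ARG", acidic = "GLU", distance = 3.5))
  rep <- run_design_pipeline(donor, acceptor)
  expect_equal(unname(rep$counts), c(1L, 2L, 0L))
  expect_equal(nrow(rep$candidates), 2L)
  # classification column is element-wise classify_effect of the ddg column
  expect_identical(rep$candidates$effect,
                   classify_effect(rep$candidates$ddg_mut))
  # deterministic given identical inputs
  rep2 <- run_design_pipeline(donor, acceptor)
  expect_identical(rep$candidates, rep2$candidates)
  # ensemble mode runs and keeps the bookkeeping identity
  ens <- jitter_ensemble(donor, 0.15, 25, seed = 4)
  rep3 <- run_design_pipeline(donor, acceptor, donor_ensemble = ens)
  expect_equal(sum(rep3$counts), nrow(rep3$donor_bridges))
})
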