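test_that("titratable sites are found with model pKas and termini", {
  s <- make_toy_structure(n_residues = 20, planted_pairs = data.frame(
    basic = "ARG", acidic = "GLU", distance = 3.5))
  sites <- find_titratable_sites(s)
  expect_setequal(sites$site_kind, c("ARG", "GLU", "NTERM", "CTERM"))
  expect_equal(nrow(sites), 4L)
  expect_equal(sites$model_pka[sites$site_kind == "GLU"], 4.4)
  expect_true(sites$is_acid[sites$site_kind == "GLU"])
  expect_false(sites$is_acid[sites$site_kind == "ARG"])
})

test_that("a disulfide-bonded cysteine pair is not titratable", {
  df <- data.frame(
    name = rep(c("CA", "CB", "SG"), 2),
    resname = "CYS", resnum = rep(1:2, each = 3),
    x = c(0, 1.5, 3.0, 5.0, 4.0, 5.0), y = c(0, 0, 0, 0, 0, 2.0), z = 0)
  paired <- df
  paired$x[6] <- 3.0; paired$y[6] <- 2.0   # SG-SG distance 2.0 < 2.3
  s_bonded <- flat_structure(paired)
  expect_false("CYS" %in%
                 suppressWarnings(find_titratable_sites(s_bonded))$site_kind)
  free <- df
  free$x[6] <- 8.0; free$y[6] <- 0          # SG-SG distance 5.0
  s_free <- flat_structure(free)
  expect_equal(
    sum(suppressWarnings(find_titratable_sites(s_free))$site_kind == "CYS"),
    2L)
})

test_that("an acid missing one charged atom still titrates, with a warning", {
  df <- data.frame(name = c("CA", "CB", "OE1"), resname = "GLU", resnum = 1L,
                   x = c(0, 1.5, 3), y = 0, z = 0)
  w <- capture_warnings(sites <- find_titratable_sites(flat_structure(df)))
  expect_true(any(grepl("charged atoms", w)))
  glu <- sites[sites$site_kind == "GLU", ]
  expect_equal(nrow(glu), 1L)
  expect_identical(glu$atoms[[1L]], "OE1")
})

test_that("mean-field pKa shifts have the expected structure", {
  # isolated acid, no neighbours, no partners: model pKa unchanged
  iso <- flat_structure(data.frame(name = c("OE1", "OE2"), resname = "GLU",
                                   resnum = 1L, x = c(0, 2.2), y = 0, z = 0))
  m <- suppressWarnings(effective_pkas(iso))
  expect_equal(m$sites$effective_pka[m$sites$site_kind == "GLU"], 4.4)
  # fully buried acid with no partners: model pKa + born_scale exactly
  crowd <- data.frame(name = "CA", resname = "ALA",
                      resnum = 1L + seq_len(45),
                      x = rep(seq(2.5, 6.5, length.out = 9), 5),
                      y = rep(1:5, each = 9), z = 0.5)
  bur <- flat_structure(rbind(
    data.frame(name = c("OE1", "OE2"), resname = "GLU", resnum = 1L,
               x = c(0, 2.2), y = 0, z = 0), crowd))
  mb <- suppressWarnings(effective_pkas(bur))
  glu_pka <- mb$sites$effective_pka[mb$sites$site_kind == "GLU"]
  expect_equal(glu_pka, 4.4 + 1.5)
  # a protonated base nearby lowers an acid's pKa (one-step hand value)
  pair <- flat_structure(data.frame(
    name = c("OE1", "OE2", "NH1", "NH2"),
    resname = c("GLU", "GLU", "ARG", "ARG"), resnum = c(1L, 1L, 2L, 2L),
    x = c(0, -2.2, 4, 6.2), y = 0, z = 0))
  mp <- suppressWarnings(effective_pkas(pair))
  glu2 <- mp$sites$effective_pka[mp$sites$site_kind == "GLU"]
  expect_lt(glu2, 4.4)
  # hand computation of the first iteration: ARG charge ~ +1 at pH 2.5,
  # centroid distance 6.2 A, shift = -332/(20*6.2)/(ln10 * R * T)
  lnRT <- log(10) * 1.9872041e-3 * 298.15
  expect_equal(glu2, 4.4 - (332 / (20 * 6.2)) / lnRT, tolerance = 0.05)
  expect_true(mp$converged)
})

test_that("mean-field result is independent of site ordering", {
  s <- make_toy_structure(n_residues = 30, planted_pairs = data.frame(
    basic = c("ARG", "LYS"), acidic = c("GLU", "ASP"),
    distance = c(3.5, 4.2)))
  sites <- find_titratable_sites(s)
  m1 <- effective_pkas(s, sites = sites)
  perm <- rev(seq_len(nrow(sites)))
  m2 <- effective_pkas(s, sites = sites[perm, ])
  expect_equal(m2$sites$effective_pka[order(perm)],
               m1$sites$effective_pka, tolerance = 1e-6)
  expect_true(m1$converged && m1$iterations < 50)
})

test_that("Henderson-Hasselbalch charges behave at the midpoint and limits", {
  m <- one_site_model("GLU", 4.4, 5.0, is_acid = TRUE)
  st <- protonation_state(m, 5.0)
  expect_equal(st$theta, 0.5)
  expect_equal(st$charge, -0.5)
  st2 <- protonation_state(m, 2.0)
  expect_gt(st2$theta, 0.999)
  # doubly protonated histidine is +1 at pH 2.5, neutral at pH 8
  mh <- one_site_model("HIS", 6.3, 6.3, is_acid = FALSE)
  expect_gt(protonation_state(mh, 2.5)$charge, 0.99)
  expect_lt(protonation_state(mh, 8.0)$charge, 0.02)
})

test_that("net charge curves are monotone and sum per-site charges", {
  s <- make_toy_structure(n_residues = 25, planted_pairs = data.frame(
    basic = "LYS", acidic = "ASP", distance = 3.6))
  m <- effective_pkas(s)
  grid <- seq(0, 14, by = 0.25)
  curve <- net_charge_curve(m, grid)
  expect_true(all(diff(curve$q) <= 1e-12))
  # brute-force per-site sum at a few pH values
  for (ph in c(2.5, 7, 11)) {
    manual <- sum(vapply(seq_len(nrow(m$sites)), function(i) {
      th <- 1 / (1 + 10^(ph - m$sites$effective_pka[i]))
      if (m$sites$is_acid[i]) -(1 - th) else th
    }, numeric(1)))
    expect_equal(curve$q[curve$ph == ph], manual)
  }
  # symmetric acid/base pair crosses zero at the midpoint pH
  msym <- one_site_model("GLU", 4, 4, TRUE)
  msym$sites <- rbind(msym$sites, msym$sites)
  msym$sites$site_kind[2] <- "LYS"; msym$sites$is_acid[2] <- FALSE
  msym$sites$model_pka[2] <- 10; msym$sites$effective_pka[2] <- 10
  expect_equal(net_charge_curve(msym, 7)$q, 0, tolerance = 1e-12)
})

test_that("Wyman integration matches the one-site closed form", {
  m <- one_site_model("GLU", 4.0, 5.0, is_acid = TRUE)
  got <- ph_stability_delta(m, NULL, 7, 2)
  want <- oracle_one_acid_delta(5.0, 4.0, 7, 2)
  expect_equal(got, want, tolerance = 1e-4)
  # antisymmetry and interval additivity
  expect_equal(ph_stability_delta(m, NULL, 2, 7), -got, tolerance = 1e-12)
  expect_equal(ph_stability_delta(m, NULL, 7, 4.5) +
                 ph_stability_delta(m, NULL, 4.5, 2), got, tolerance = 1e-6)
  # identical folded and unfolded pKas integrate to zero
  m0 <- one_site_model("GLU", 4.4, 4.4, TRUE)
  expect_equal(ph_stability_delta(m0, NULL, 7, 2), 0, tolerance = 1e-12)
})
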