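# Charge-map and aggregation-propensity fields and their domain sums.

test_that("atomic charge field matches the all-pairs oracle exactly", {
  for (seed in c(1, 4)) {
    s <- random_cluster(20, seed = seed)
    sas <- shrake_rupley(s)
    ex <- exposed_residues(side_chain_sasa(sas, s))
    expect_equal(atomic_scm(s, ex), oracle_scm(s, ex))
  }
  # one-term and out-of-range cases from the analytic catalogue
  close <- make_toy_structure("pair_close")
  sc <- atomic_scm(close$structure, c("H:1", "L:1"))
  expect_equal(sc, close$sheet$scm)
  far <- make_toy_structure("pair_far")
  expect_equal(atomic_scm(far$structure, c("H:1", "L:1")), c(0, 0))
  # empty exposed set warns and zeroes
  expect_warning(z <- atomic_scm(close$structure, character(0)), "empty")
  expect_equal(z, c(0, 0))
})

test_that("aggregation-propensity field matches the direct-summation oracle", {
  for (seed in c(3, 9)) {
    s <- random_cluster(12, seed = seed)
    sas <- shrake_rupley(s)
    expect_equal(atomic_sap(s, sas), unname(oracle_sap(s, sas)),
                 tolerance = 1e-10)
  }
  # hydrophobicity 0 residues contribute nothing
  s <- random_cluster(6, seed = 2)
  s$atoms$resname <- "GLY"   # glycine-centred scale: GLY exactly 0
  s$atoms$aa <- "G"
  sas <- shrake_rupley(s)
  expect_equal(atomic_sap(s, sas), rep(0, 6))
  # missing table entries are rejected
  expect_error(atomic_sap(s, sas, scale = c(ALA = 0.1)), "hydrophobicity")
})

test_that("domain sums implement the positive/negative split identities", {
  s <- scored_fixture()$structure
  dm <- assign_domains(s)
  sas <- shrake_rupley(s)
  ex <- exposed_residues(side_chain_sasa(sas, s))
  field <- atomic_scm(s, ex)
  d <- domain_scm(field, dm, s)
  sheet <- scored_fixture()$sheet$domain
  for (nm in names(sheet)) {
    prop <- sub("_(CDR.*|Hv|Lv|Fv)$", "", nm)
    reg <- sub("^SCM_(pos|neg)_", "", nm)
    expect_equal(d[d$region == reg, prop], sheet[[nm]],
                 info = nm, tolerance = 1e-12)
  }
  # SCM_pos - SCM_neg equals the plain regional sum, for every region
  mem <- abprop:::atom_membership(s, dm)
  expect_equal(d$SCM_pos - d$SCM_neg, as.vector(field %*% mem))
  # both parts are nonnegative; zero field gives all-zero sums
  expect_true(all(d$SCM_pos >= 0 & d$SCM_neg >= 0))
  d0 <- domain_scm(rep(0, nrow(s$atoms)), dm, s)
  expect_true(all(d0$SCM_pos == 0 & d0$SCM_neg == 0))

  # positive-part sums ignore negative values and zeroing them changes nothing
  sap_field <- c(0.3, -0.1, 0.2, -0.4, 0.1)
  dp <- domain_sap_pos(sap_field, dm, s)
  dp2 <- domain_sap_pos(pmax(sap_field, 0), dm, s)
  expect_equal(dp, dp2)
  expect_true(all(dp$SAP_pos >= 0))
  expect_equal(domain_sap_pos(-abs(sap_field), dm, s)$SAP_pos, rep(0, 10))
})

test_that("region additivity: Fv = Hv + Lv and CDR = sum of the six CDRs", {
  s <- random_cluster(16, seed = 8)
  # place residues into CDR-range numbers so all regions are populated
  s$atoms$resno <- c(27, 53, 96, 100, 30, 60, 70, 80,
                     25, 52, 90, 95, 40, 60, 70, 80)
  s$atoms$key <- abprop:::residue_key(s$atoms$role, s$atoms$resno)
  desc <- score_structure(s, n_points = 240)
  v <- descriptor_vector(desc)
  for (p in ab_properties()) {
    expect_equal(v[paste0(p, "_Fv")],
                 v[paste0(p, "_Hv")] + v[paste0(p, "_Lv")],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(v[paste0(p, "_CDR")],
                 sum(v[paste0(p, "_CDR", c("H1", "H2", "H3",
                                           "L1", "L2", "L3"))]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("scores are rigid-motion invariant and scale linearly in charge", {
  s <- random_cluster(10, seed = 6)
  sas <- shrake_rupley(s)
  ex <- exposed_residues(side_chain_sasa(sas, s))
  base <- atomic_scm(s, ex)

  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  s2 <- s
  s2$coords[, , 1] <- sweep(s$coords[, , 1] %*% R, 2, c(5, -3, 2), "+")
  sas2 <- shrake_rupley(s2)
  ex2 <- exposed_residues(side_chain_sasa(sas2, s2))
  expect_setequal(ex2, ex)
  expect_equal(atomic_scm(s2, ex2), base, tolerance = 1e-9)

  # doubling charges doubles both split sums exactly
  s3 <- s
  s3$atoms$charge <- 2 * s$atoms$charge
  expect_equal(atomic_scm(s3, ex), 2 * base)

  # scaling hydrophobicities scales the positive part linearly
  sap1 <- atomic_sap(s, sas)
  sap3 <- atomic_sap(s, sas, scale = 3 * hydrophobicity_scale())
  expect_equal(sap3, 3 * sap1)
})

test_that("ensemble statistics use denominator N and flag undefined spread", {
  st <- ensemble_stats(list(c(a = 1), c(a = 3)))
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)           # population sd of {1, 3}
  expect_equal(st$rel_sd, 0.5)
  expect_equal(ensemble_stats(list(c(a = 5)))$sd, 0)
  expect_equal(ensemble_stats(list(c(a = 4), c(a = 4)))$rel_sd, 0)
  # zero mean with spread: undefined sentinel, not infinity
  st2 <- ensemble_stats(list(c(a = -1), c(a = 1)))
  expect_true(is.na(st2$rel_sd))

  # identical frames give zero ensemble spread through the full pipeline
  frames <- make_toy_structure("pair_frames")$structure
  desc <- score_structure(frames, n_points = 240)
  expect_true(all(desc$sd == 0))
})
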