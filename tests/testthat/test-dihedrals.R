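# Dihedral geometry and the psi/stabilization-center association statistic.

test_that("closed-form planar cases give 0 and 180 exactly", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(2, 1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(0, 1, 0)), 0)
})

test_that("the sign convention matches the reference implementation", {
  # right-angle fixture
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]), 90)
  # cross-check a batch of random quadruples against bio3d
  set.seed(31)
  for (k in 1:25) {
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    ref <- bio3d::torsion.xyz(as.vector(t(q)), atm.inc = 4)
    ours <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(ours, sctraj:::wrap_deg(ref), tolerance = 1e-8)
  }
})

test_that("angles are invariant under rigid transforms and antisymmetric", {
  set.seed(13)
  for (k in 1:10) {
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    a0 <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    tr <- random_rigid(k)
    qt <- q %*% t(tr$R) + matrix(tr$t, 4, 3, byrow = TRUE)
    at_ <- dihedral_angle(qt[1, ], qt[2, ], qt[3, ], qt[4, ])
    expect_lt(abs(sctraj:::wrap_deg(at_ - a0)), 1e-6)
    # reversing the atom order leaves the dihedral unchanged
    ar <- dihedral_angle(q[4, ], q[3, ], q[2, ], q[1, ])
    expect_lt(abs(sctraj:::wrap_deg(ar - a0)), 1e-6)
    # mirroring flips the sign
    qm <- q; qm[, 3] <- -qm[, 3]
    am <- dihedral_angle(qm[1, ], qm[2, ], qm[3, ], qm[4, ])
    expect_lt(abs(sctraj:::wrap_deg(am + a0)) %% 360, 1e-6)
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), class = "sctraj_degenerate")
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), class = "sctraj_degenerate")
})

test_that("an ideal trans peptide gives omega = 180 in every frame", {
  traj <- trans_peptide_traj(4)
  om <- residue_dihedral_series(traj, "A", 2, "omega")
  expect_equal(length(om$values_deg), 4)
  expect_true(all(abs(abs(om$values_deg) - 180) < 0.1))
  expect_equal(classify_proline_isomer(om$values_deg),
               rep("trans", 4))
})

test_that("terminal residues without the needed neighbour are rejected", {
  traj <- trans_peptide_traj(1)
  expect_error(residue_dihedral_series(traj, "A", 2, "psi"),
               class = "sctraj_not_computable")
  expect_error(residue_dihedral_series(traj, "A", 1, "phi"),
               class = "sctraj_not_computable")
})

test_that("cis/trans classification is inclusive at 90 degrees", {
  expect_equal(classify_proline_isomer(c(180, 5, 90, -90, 91)),
               c("trans", "cis", "cis", "cis", "trans"))
  expect_error(classify_proline_isomer(NA_real_), class = "sctraj_invalid")
})

test_that("generator psi playback is reproduced within jitter", {
  asm <- default_asm()
  ps <- default_plant_spec(asm, n_frames = 40, fidelity = 1, seed = 21)
  out <- plant_and_roll(asm, ps)
  psi <- residue_dihedral_series(out$trajectory, "D", 193, "psi")
  err <- abs(sctraj:::wrap_deg(psi$values_deg - out$truth$psi_targets))
  expect_lt(max(err), 5)
  inw <- sctraj:::in_window(psi$values_deg, psi_window(-45, 0))
  expect_equal(inw, out$truth$window_state)
})

test_that("perfect anti-coupling gives occ_in 0, occ_out 1 and minimal p", {
  sim <- simulate_coupled_series(200, occupancy = 0.5, fidelity = 1,
                                 sense = "anti", seed = 3,
                                 mode = "deterministic")
  a <- correlate_sc_dihedral(sim$presence, sim$psi, n_perm = 199, seed = 4)
  expect_equal(a$occ_in_window, 0)
  expect_equal(a$occ_out_window, 1)
  expect_equal(a$perm_p, 1 / 200)
  expect_lt(a$odds_ratio, 1)
})

test_that("independence gives a near-unit odds ratio and large p", {
  ok_or <- 0; ok_p <- 0; n_rep <- 20
  for (k in seq_len(n_rep)) {
    sim <- simulate_coupled_series(2000, occupancy = 0.5, fidelity = 0.5,
                                   seed = 400 + k)
    a <- correlate_sc_dihedral(sim$presence, sim$psi, n_perm = 199,
                               seed = 500 + k)
    ok_or <- ok_or + (a$odds_ratio >= 0.7 && a$odds_ratio <= 1.4)
    ok_p <- ok_p + (a$perm_p > 0.05)
  }
  expect_gte(ok_or / n_rep, 0.9)
  expect_gte(ok_p / n_rep, 0.9)
})

test_that("odds ratios increase with planted coupling fidelity", {
  ors <- vapply(c(0.5, 0.7, 0.9, 1.0), function(f) {
    sim <- simulate_coupled_series(1500, occupancy = 0.5, fidelity = f,
                                   sense = "pro", seed = 42)
    correlate_sc_dihedral(sim$presence, sim$psi, n_perm = 99,
                          seed = 7)$odds_ratio
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("degenerate margins flag the association as undefined", {
  # stabilization center always present
  a <- correlate_sc_dihedral(rep(TRUE, 50), runif(50, -200, 160),
                             n_perm = 99, seed = 1)
  expect_true(a$flagged)
  expect_true(is.na(a$perm_p))
  # every frame on one side of the window
  b <- correlate_sc_dihedral(rep(c(TRUE, FALSE), 25), rep(100, 50),
                             n_perm = 99, seed = 1)
  expect_true(b$flagged)
})

test_that("any/all aggregation over multiple psi series differs as stated", {
  s1 <- c(-20, 100, -20, 100)
  s2 <- c(100, 100, -20, 100)
  pres <- c(TRUE, FALSE, TRUE, FALSE)
  a_any <- correlate_sc_dihedral(pres, list(s1, s2), n_perm = 3, seed = 1,
                                 aggregate = "any")
  a_all <- correlate_sc_dihedral(pres, list(s1, s2), n_perm = 3, seed = 1,
                                 aggregate = "all")
  expect_equal(sum(a_any$table[c("a", "b")]), 2)  # frames 1 and 3 in-window
  expect_equal(sum(a_all$table[c("a", "b")]), 1)  # only frame 3
})
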