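# The synthetic assembly / trajectory generator and its ground truth.

test_that("the builder produces the requested double-ring architecture", {
  asm <- default_asm()
  at <- asm$frame$atoms
  expect_equal(sort(unique(at$chain)), LETTERS[1:12])
  hc <- asm$topology$hemichannel_of
  expect_equal(unname(hc[LETTERS[1:6]]), rep("HC1", 6))
  expect_equal(unname(hc[LETTERS[7:12]]), rep("HC2", 6))
  # a single chain per ring still gives two chains
  asm2 <- build_toy_assembly(assembly_spec(chains_per_ring = 1, seed = 1))
  expect_equal(sort(unique(asm2$frame$atoms$chain)), c("A", "B"))
})

test_that("residue numbering fills the extracellular loop ranges", {
  asm <- default_asm()
  a_res <- sort(unique(asm$frame$atoms$res_seq[asm$frame$atoms$chain == "A"]))
  expect_equal(a_res, c(47:73, 177:203))
  # Cx43 loop cysteines are present with SG atoms
  cys <- asm$frame$atoms[asm$frame$atoms$chain == "A" &
                           asm$frame$atoms$res_name == "CYS", ]
  expect_equal(sort(unique(cys$res_seq)), c(54, 61, 65, 187, 192, 198))
  expect_true(all(c(54, 61, 65, 187, 192, 198) %in%
                    cys$res_seq[cys$atom_name == "SG"]))
})

test_that("the builder and generator are deterministic given the seed", {
  a1 <- build_toy_assembly(assembly_spec(seed = 7))
  a2 <- build_toy_assembly(assembly_spec(seed = 7))
  expect_identical(a1$frame$xyz, a2$frame$xyz)
  ps <- default_plant_spec(a1, n_frames = 4, seed = 7)
  t1 <- plant_and_roll(a1, ps)
  t2 <- plant_and_roll(a2, ps)
  expect_identical(t1$trajectory$coords, t2$trajectory$coords)
  expect_identical(t1$truth$presence, t2$truth$presence)
})

test_that("generator output satisfies the structural invariants", {
  asm <- default_asm()
  out <- plant_and_roll(asm, default_plant_spec(asm, n_frames = 3,
                                                seed = 12))
  expect_true(sctraj:::validate_trajectory(out$trajectory))
  f <- tempfile(fileext = ".pdb")
  write_pdb(out$trajectory, f)
  rt <- read_pdb(f)
  expect_equal(n_frames(rt), 3)
  expect_equal(rt$atoms$res_seq, out$trajectory$atoms$res_seq)
})

test_that("end-to-end recovery is exact in deterministic mode", {
  asm <- default_asm()
  ps <- default_plant_spec(asm, n_frames = 50, seed = 33)
  out <- plant_and_roll(asm, ps)
  ser <- classify_series(sc_time_series(out$trajectory), asm$topology)
  truth <- out$truth$pairs
  expect_equal(nrow(ser$pairs), nrow(truth))
  key_r <- sctraj:::pair_key(ser$pairs$uid_u, ser$pairs$uid_v)
  m <- match(truth$key, key_r)
  expect_false(any(is.na(m)))
  expect_equal(ser$pairs$occupancy[m], truth$realized_occupancy)
  expect_equal(ser$pairs$class[m], truth$class)
  # per-frame presence matches, not just the occupancy
  expect_equal(unname(ser$presence[, m]), unname(out$truth$presence))
})

test_that("stochastic occupancies land within binomial tolerance", {
  asm <- default_asm()
  scs <- data.frame(chain_u = "D", res_seq_u = 55, chain_v = "G",
                    res_seq_v = 56, support = 9, occupancy = 0.7)
  ps <- plant_spec(planted_scs = scs, n_frames = 120, mode = "bernoulli",
                   seed = 3)
  out <- plant_and_roll(asm, ps)
  ser <- sc_time_series(out$trajectory)
  q <- 0.7
  tol <- 3 * sqrt(q * (1 - q) / 120)
  expect_lt(abs(ser$pairs$occupancy - q), tol)
  expect_equal(ser$pairs$occupancy,
               unname(out$truth$pairs$realized_occupancy))
})

test_that("open disulfide mode leaves no detectable bond in any frame", {
  asm <- default_asm()
  ps <- default_plant_spec(asm, n_frames = 4, disulfide_mode = "open",
                           seed = 5)
  out <- plant_and_roll(asm, ps)
  for (f in seq_len(4))
    expect_equal(nrow(detect_disulfides(get_frame(out$trajectory, f))), 0)
})

test_that("close disulfide mode plants exactly the three bonds per chain", {
  asm <- default_asm()
  ps <- default_plant_spec(asm, n_frames = 2, seed = 6)
  out <- plant_and_roll(asm, ps)
  ss <- detect_disulfides(get_frame(out$trajectory, 1))
  expect_equal(nrow(ss), 36)  # 3 bonds x 12 chains
  expect_true(all(ss$chain_u == ss$chain_v))
  per_chain <- split(paste(ss$res_seq_u, ss$res_seq_v), ss$chain_u)
  for (ch in names(per_chain))
    expect_setequal(per_chain[[ch]], c("54 198", "61 192", "65 187"))
  expect_true(all(abs(ss$sg_dist_A - 2.05) < 0.3))
})

test_that("conflicting planted specifications are rejected", {
  asm <- default_asm()
  dup <- data.frame(chain_u = c("D", "D"), res_seq_u = 55,
                    chain_v = c("G", "G"), res_seq_v = 56,
                    support = 9, occupancy = c(0.5, 0.9))
  expect_error(plant_and_roll(asm, plant_spec(planted_scs = dup,
                                              n_frames = 2)),
               class = "sctraj_spec")
  ghost <- data.frame(chain_u = "D", res_seq_u = 999, chain_v = "G",
                      res_seq_v = 56, support = 9, occupancy = 0.5)
  expect_error(plant_and_roll(asm, plant_spec(planted_scs = ghost,
                                              n_frames = 2)),
               class = "sctraj_spec")
  expect_error(plant_spec(planted_scs = data.frame(
    chain_u = "D", res_seq_u = 55, chain_v = "G", res_seq_v = 56,
    support = 12, occupancy = 0.5)), class = "sctraj_spec")
})

test_that("psi coupling with fidelity 1 is a perfect anti-switch", {
  asm <- default_asm()
  ps <- default_plant_spec(asm, n_frames = 30, fidelity = 1, seed = 8)
  out <- plant_and_roll(asm, ps)
  expect_equal(out$truth$window_state,
               !out$truth$presence[, out$truth$plant_spec$psi_coupling$coupled_pair])
})
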