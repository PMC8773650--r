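# Contact criterion, stabilization centers and disulfides in single frames.

two_carbon_frame <- function(d) {
  make_frame(data.frame(
    chain = c("A", "A"), res_seq = c(1, 20), res_name = "ALA",
    atom_name = "CA", element = "C",
    x = c(0, d), y = 0, z = 0))
}

test_that("the contact inequality is strict around the vdW + margin cutoff", {
  vdw <- default_vdw_table()
  rc <- vdw_radius(vdw, "C")  # 1.70
  f_in <- two_carbon_frame(2 * rc + 0.9)
  f_out <- two_carbon_frame(2 * rc + 1.1)
  r_in <- residue_min_distance(f_in$xyz[1, , drop = FALSE],
                               f_in$xyz[2, , drop = FALSE], "C", "C")
  r_out <- residue_min_distance(f_out$xyz[1, , drop = FALSE],
                                f_out$xyz[2, , drop = FALSE], "C", "C")
  expect_true(r_in$in_contact)
  expect_false(r_out$in_contact)
  expect_equal(r_in$min_dist_A, 2 * rc + 0.9)
  # coincident atoms: distance zero, in contact
  r0 <- residue_min_distance(matrix(0, 1, 3), matrix(0, 1, 3), "C", "C")
  expect_true(r0$in_contact)
  expect_equal(r0$min_dist_A, 0)
  # exactly at the cutoff: "closer than" excludes equality
  r_eq <- residue_min_distance(matrix(0, 1, 3),
                               matrix(c(2 * rc + 1, 0, 0), 1, 3), "C", "C")
  expect_false(r_eq$in_contact)
})

test_that("degenerate residues (no heavy atoms) are rejected", {
  expect_error(
    residue_min_distance(matrix(0, 1, 3), matrix(1, 1, 3), "H", "C"),
    class = "sctraj_degenerate")
})

test_that("find_contacts flags long-range pairs by chain and separation", {
  fr <- make_frame(data.frame(
    chain = c("A", "A", "B"), res_seq = c(10, 15, 3), res_name = "ALA",
    atom_name = "CA", element = "C",
    x = c(0, 3, 0), y = c(0, 0, 3), z = 0))
  fc <- find_contacts(fr)
  expect_equal(nrow(fc), 3)  # all three pairs within 4.4
  k <- sctraj:::pair_key(fc$uid_u, fc$uid_v)
  expect_false(fc$is_long_range[k == sctraj:::pair_key("A:10", "A:15")])
  expect_true(all(fc$is_long_range[grepl("B:3", k)]))
})

test_that("cell-list contacts equal the brute-force oracle on random frames",
{
  for (seed in 1:12) {
    fr <- random_frame(60, seed)
    fc <- find_contacts(fr)
    bf <- brute_force_contacts(fr)
    expect_identical(sort(sctraj:::pair_key(fc$uid_u, fc$uid_v)),
                     sort(sctraj:::pair_key(bf$uid_u, bf$uid_v)))
    m <- match(sctraj:::pair_key(fc$uid_u, fc$uid_v),
               sctraj:::pair_key(bf$uid_u, bf$uid_v))
    expect_equal(fc$min_dist_A, bf$min_dist_A[m], tolerance = 1e-12)
    expect_equal(fc$is_long_range, bf$is_long_range[m])
  }
})

test_that("stabilization centers equal the brute-force oracle", {
  for (seed in 1:8) {
    fr <- random_frame(50, seed + 100)
    sc <- find_stabilization_centers(fr)
    bf <- brute_force_scs(fr)
    expect_identical(sort(sctraj:::pair_key(sc$uid_u, sc$uid_v)),
                     sort(sctraj:::pair_key(bf$uid_u, bf$uid_v)))
    if (nrow(sc) > 0) {
      m <- match(sctraj:::pair_key(sc$uid_u, sc$uid_v),
                 sctraj:::pair_key(bf$uid_u, bf$uid_v))
      expect_equal(sc$support_count, bf$support_count[m])
    }
  }
})

# A controlled two-chain fixture: triplets around A:10 and B:20 whose CA
# atoms all sit within one tight cluster -> all 9 triplet pairs in contact.
support_fixture <- function(central_only = FALSE) {
  rows <- list()
  for (i in 1:3) {
    for (ch in c("A", "B")) {
      rs <- if (ch == "A") 8 + i else 18 + i
      central <- (ch == "A" && rs == 10) || (ch == "B" && rs == 20)
      base <- if (central_only && !central) {
        c(100 * i + ifelse(ch == "A", 0, 50), 100, 100)
      } else {
        c(ifelse(ch == "A", 0, 1.5) + 0.2 * i, 0.3 * i, 0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, res_seq = rs, res_name = "ALA", atom_name = "CA",
        element = "C", x = base[1], y = base[2], z = base[3],
        stringsAsFactors = FALSE)
    }
  }
  # pad the chains so the triplets are not cut by termini
  for (ch in c("A", "B")) for (rs in c(5, 30, 40)) {
    rows[[length(rows) + 1]] <- data.frame(
      chain = ch, res_seq = rs, res_name = "ALA", atom_name = "CA",
      element = "C", x = 500 + rs + ifelse(ch == "A", 0, 60), y = 500,
      z = 0, stringsAsFactors = FALSE)
  }
  make_frame(do.call(rbind, rows))
}

test_that("a fully interacting neighbourhood yields support 9", {
  fr <- support_fixture()
  sc <- find_stabilization_centers(fr)
  key <- sctraj:::pair_key(sc$uid_u, sc$uid_v)
  expect_true(sctraj:::pair_key("A:10", "B:20") %in% key)
  row <- sc[key == sctraj:::pair_key("A:10", "B:20"), ]
  expect_equal(row$support_count, 9)
})

test_that("an isolated central contact is not a stabilization center", {
  fr <- support_fixture(central_only = TRUE)
  fc <- find_contacts(fr)
  expect_true(sctraj:::pair_key("A:10", "B:20") %in%
                sctraj:::pair_key(fc$uid_u, fc$uid_v))
  sc <- find_stabilization_centers(fr)
  expect_false(sctraj:::pair_key("A:10", "B:20") %in%
                 sctraj:::pair_key(sc$uid_u, sc$uid_v))
})

test_that("short-range intra-chain pairs are never stabilization centers", {
  # residues 5 apart in one chain, geometrically identical to the fixture
  rows <- do.call(rbind, lapply(1:6, function(i) data.frame(
    chain = "A", res_seq = c(9, 10, 11, 14, 15, 16)[i], res_name = "ALA",
    atom_name = "CA", element = "C",
    x = c(0, 0.2, 0.4, 1.5, 1.7, 1.9)[i], y = 0.3 * (i %% 3), z = 0)))
  fr <- make_frame(rows)
  sc <- find_stabilization_centers(fr)
  expect_equal(nrow(sc), 0)
})

test_that("contact and SC sets behave monotonically in their parameters", {
  fr <- random_frame(40, 77)
  small <- find_contacts(fr, params = contact_params(margin_A = 0.5))
  big <- find_contacts(fr, params = contact_params(margin_A = 2))
  expect_true(all(sctraj:::pair_key(small$uid_u, small$uid_v) %in%
                    sctraj:::pair_key(big$uid_u, big$uid_v)))
  loose <- find_stabilization_centers(fr, sparams = sc_params(5))
  tight <- find_stabilization_centers(fr, sparams = sc_params(8))
  expect_true(all(sctraj:::pair_key(tight$uid_u, tight$uid_v) %in%
                    sctraj:::pair_key(loose$uid_u, loose$uid_v)))
  # SC set is a subset of the long-range contact set
  sc <- find_stabilization_centers(fr)
  fc <- find_contacts(fr)
  lr <- fc[fc$is_long_range, ]
  expect_true(all(sctraj:::pair_key(sc$uid_u, sc$uid_v) %in%
                    sctraj:::pair_key(lr$uid_u, lr$uid_v)))
})

test_that("hydrogens never change contacts when use_heavy_only is set", {
  fr <- random_frame(30, 5)
  # add a hydrogen shell around every atom
  at <- fr$atoms
  h <- at
  h$atom_name <- "H"
  h$element <- "H"
  h$is_heavy <- FALSE
  both <- rbind(at, h)
  xyz <- rbind(fr$xyz, fr$xyz + 0.9)
  o <- order(both$chain, both$res_seq, both$icode)
  fr_h <- sctraj:::new_frame(both[o, ], xyz[o, ])
  fc1 <- find_contacts(fr)
  fc2 <- find_contacts(fr_h)
  expect_identical(sort(sctraj:::pair_key(fc1$uid_u, fc1$uid_v)),
                   sort(sctraj:::pair_key(fc2$uid_u, fc2$uid_v)))
  sc1 <- find_stabilization_centers(fr)
  sc2 <- find_stabilization_centers(fr_h)
  expect_identical(sort(sctraj:::pair_key(sc1$uid_u, sc1$uid_v)),
                   sort(sctraj:::pair_key(sc2$uid_u, sc2$uid_v)))
})

test_that("terminal truncation: proportional admits, strict rejects", {
  # chain ends right at the central residues: triplets have 2x2 = 4 pairs,
  # all in contact -> proportional threshold ceiling(7*4/9) = 4 admits,
  # strict threshold 7 rejects
  rows <- do.call(rbind, lapply(list(
    c("A", 1, 0, 0), c("A", 2, 0.2, 0.3),
    c("B", 1, 1.5, 0), c("B", 2, 1.7, 0.3)), function(r) data.frame(
      chain = r[1], res_seq = as.integer(r[2]), res_name = "ALA",
      atom_name = "CA", element = "C", x = as.numeric(r[3]),
      y = as.numeric(r[4]), z = 0)))
  fr <- make_frame(rows)
  prop <- find_stabilization_centers(
    fr, sparams = sc_params(7, "proportional"))
  strict <- find_stabilization_centers(fr, sparams = sc_params(7, "strict"))
  expect_gt(nrow(prop), 0)
  expect_equal(prop$support_count[1], 4)
  expect_equal(nrow(strict), 0)
})

test_that("disulfide detection pairs SG atoms greedily under the cutoff", {
  mk_cys <- function(chain, rs, sgx, sgy = 0) data.frame(
    chain = chain, res_seq = rs, res_name = "CYS",
    atom_name = c("CA", "SG"), element = c("C", "S"),
    x = c(sgx - 1.5, sgx), y = c(sgy, sgy), z = 0)
  # planted bonds at 2.05 A: (54, 198), (61, 192), (65, 187)
  rows <- rbind(
    mk_cys("A", 54, 0), mk_cys("A", 198, 2.05),
    mk_cys("A", 61, 20), mk_cys("A", 192, 22.05),
    mk_cys("A", 65, 40), mk_cys("A", 187, 42.05))
  fr <- make_frame(rows)
  ss <- detect_disulfides(fr)
  expect_equal(nrow(ss), 3)
  expect_equal(sort(paste(ss$res_seq_u, ss$res_seq_v)),
               sort(c("54 198", "61 192", "65 187")))
  expect_true(all(abs(ss$sg_dist_A - 2.05) < 1e-9))

  # 3.5 A is beyond the 2.5 A cutoff
  fr2 <- make_frame(rbind(mk_cys("A", 1, 0), mk_cys("A", 30, 3.5)))
  expect_equal(nrow(detect_disulfides(fr2)), 0)

  # three mutually close SGs: the two closest pair up, the third is left
  fr3 <- make_frame(rbind(mk_cys("A", 1, 0), mk_cys("A", 30, 2.0),
                          mk_cys("A", 60, 0.9, 1.0)))
  ss3 <- detect_disulfides(fr3)
  expect_equal(nrow(ss3), 1)
  expect_equal(sort(c(ss3$res_seq_u, ss3$res_seq_v)), c(1, 60))

  # cysteine lacking SG: warned and skipped
  noSG <- data.frame(chain = "A", res_seq = 99, res_name = "CYS",
                     atom_name = "CA", element = "C", x = 50, y = 0, z = 0)
  expect_warning(detect_disulfides(make_frame(rbind(mk_cys("A", 1, 0), noSG))),
                 "without SG")
})
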