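# Synthetic toy assemblies and trajectories with exact ground truth.
#
# The generator emulates the architecture of a gap-junction channel: two
# parallel rings of chains (hemichannels) facing each other across an
# extracellular gap, with the configured extracellular residue ranges
# pointing into the gap.  Chains are simplified poly-alanine-like backbones
# (N, CA, C, O, CB; SG on cysteines); residues whose numbers fall in the
# connexin-43 extracellular loops take the corresponding Cx43 residue names.
#
# Planted stabilization centers are realized through dedicated "bridge"
# carbon atoms: each desired supporting contact (u', v') gets its own
# isolated interaction site, far from the rings, where one extra atom of u'
# and one of v' sit 2 A apart (well inside the carbon-carbon contact cutoff
# of 4.4 A).  This gives exact, independent control of every supporting
# contact count at the price of geometric realism, which the distance-based
# detector never sees.  "Absent" frames displace all u-side bridge atoms of
# the pair far away, switching off every supporting contact at once.

#' Specification of a synthetic two-ring assembly
#'
#' @param chains_per_ring Chains per ring (default 6, giving the 12-subunit
#'   double hexamer; two rings are always generated).
#' @param residues_per_chain Residues per chain (default 54 = the two
#'   27-residue extracellular loops; must be >= 20).  Residues are numbered
#'   into the extracellular ranges: the first range is filled first, the
#'   remainder continues from the start of the second.
#' @param ring_radius_A Ring radius in Angstrom (default 40).
#' @param inter_ring_gap_A Gap between the rings along z (default 12).
#' @param extracellular_ranges As in [topology_config()].
#' @param seed Integer seed recorded in the assembly specification and used
#'   by downstream generation.
#' @return An object of class `assembly_spec`.
#' @export
assembly_spec <- function(chains_per_ring = 6, residues_per_chain = 54,
                          ring_radius_A = 40, inter_ring_gap_A = 12,
                          extracellular_ranges = list(c(47, 73),
                                                      c(177, 203)),
                          seed = 1) {
  if (chains_per_ring < 1)
    stop_sctraj("sctraj_spec", "chains_per_ring must be >= 1")
  if (2 * chains_per_ring > 26)
    stop_sctraj("sctraj_spec", "at most 13 chains per ring (A-Z chain IDs)")
  if (residues_per_chain < 20)
    stop_sctraj("sctraj_spec", "residues_per_chain must be >= 20")
  if (ring_radius_A <= 0 || inter_ring_gap_A <= 0)
    stop_sctraj("sctraj_spec", "radius and gap must be positive")
  structure(list(chains_per_ring = as.integer(chains_per_ring),
                 residues_per_chain = as.integer(residues_per_chain),
                 ring_radius_A = ring_radius_A,
                 inter_ring_gap_A = inter_ring_gap_A,
                 extracellular_ranges = extracellular_ranges,
                 seed = as.integer(seed)),
            class = "assembly_spec")
}

# Residue numbering for one chain: fill the first extracellular range, then
# continue from the start of the second (and past its end if needed).
chain_res_numbers <- function(spec) {
  r1 <- spec$extracellular_ranges[[1]]
  n <- spec$residues_per_chain
  n1 <- min(n, r1[2] - r1[1] + 1)
  nums <- seq(r1[1], length.out = n1)
  if (n > n1) {
    r2 <- spec$extracellular_ranges[[2]]
    nums <- c(nums, seq(r2[1], length.out = n - n1))
  }
  list(numbers = nums, n_seg1 = n1)
}

# Fixed local atom offsets (A) relative to the CA position.  Chosen so that
# N->CA and CA->C are never collinear (dihedrals stay well-defined).
BACKBONE_OFFSETS <- list(
  N  = c(-0.9, -1.1, -0.3),
  CA = c(0, 0, 0),
  C  = c(0.9, -1.1, 0.3),
  O  = c(1.3, -2.2, 0.5),
  CB = c(0, 1.4, 0.5)
)
SG_OFFSET <- c(0.6, 2.3, 1.1)  # relative to CA, beyond CB

#' Build a synthetic two-ring toy assembly
#'
#' Places `2 * chains_per_ring` chains (IDs A, B, ...) on two parallel rings
#' facing each other across a gap along z; ring 1 maps to hemichannel HC1,
#' ring 2 to HC2.  Each chain carries its two extracellular segments as
#' straight strands whose range-end residues sit at the gap edge.  Residues
#' numbered like the Cx43 extracellular loops receive the Cx43 residue names
#' (so 54, 61, 65, 187, 192, 198 become cysteines with SG atoms); all other
#' residues are alanines.  Deterministic.
#'
#' @param spec An [assembly_spec()].
#' @return A list with `frame` (the assembly as a single frame),
#'   `topology` (a [topology_config()]), and `spec`.
#' @export
build_toy_assembly <- function(spec) {
  cpr <- spec$chains_per_ring
  chains <- LETTERS[seq_len(2 * cpr)]
  ring <- rep(1:2, each = cpr)
  theta <- rep(2 * pi * (seq_len(cpr) - 1) / cpr, times = 2)
  numbering <- chain_res_numbers(spec)
  nums <- numbering$numbers
  n1 <- numbering$n_seg1
  gap <- spec$inter_ring_gap_A
  R <- spec$ring_radius_A

  # guard against overlapping chains: strand anchor points of different
  # chains must stay well apart in the xy plane
  anchors <- do.call(rbind, lapply(seq_along(chains), function(k) {
    b <- c(R * cos(theta[k]), R * sin(theta[k]))
    t_hat <- c(-sin(theta[k]), cos(theta[k]))
    rbind(b, b + 10 * t_hat)
  }))
  if (cpr > 1) {
    # rings are separated along z, so only same-ring chains can collide
    ch_of <- rep(seq_along(chains), each = 2)
    ring_of <- ring[ch_of]
    D <- as.matrix(stats::dist(anchors))
    check <- outer(ch_of, ch_of, "!=") & outer(ring_of, ring_of, "==")
    if (min(D[check & upper.tri(D)]) < 15)
      stop_sctraj("sctraj_spec",
                  "chains overlap: increase ring_radius_A or reduce chains")
  }

  el_names <- local({
    els <- cx43_el_sequences()
    tab <- rbind(els$EL1, els$EL2)
    stats::setNames(unname(AA_THREE[tab$aa]), tab$res_seq)
  })

  atoms <- list()
  xyz <- list()
  for (k in seq_along(chains)) {
    zsign <- if (ring[k] == 1) -1 else 1
    base <- c(R * cos(theta[k]), R * sin(theta[k]), 0)
    t_hat <- c(-sin(theta[k]), cos(theta[k]), 0)
    for (j in seq_along(nums)) {
      if (j <= n1) {
        strand_base <- base
        z <- zsign * (gap / 2 + (n1 - j) * 3.8)
      } else {
        strand_base <- base + 10 * t_hat
        z <- zsign * (gap / 2 + (j - n1 - 1) * 3.8)
      }
      ca <- strand_base + c(0, 0, z)
      rn <- unname(el_names[as.character(nums[j])])
      if (is.na(rn)) rn <- "ALA"
      atom_names <- names(BACKBONE_OFFSETS)
      offs <- BACKBONE_OFFSETS
      if (rn == "GLY") {
        atom_names <- setdiff(atom_names, "CB")
        offs <- offs[atom_names]
      }
      if (rn == "CYS") {
        atom_names <- c(atom_names, "SG")
        offs <- c(offs, list(SG = SG_OFFSET))
      }
      atoms[[length(atoms) + 1]] <- data.frame(
        atom_name = atom_names, alt_loc = "", res_name = rn,
        chain = chains[k], res_seq = nums[j], icode = "",
        element = substr(atom_names, 1, 1), stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1]] <-
        t(vapply(offs, function(o) ca + o, numeric(3)))
    }
  }
  at <- do.call(rbind, atoms)
  at$element[at$atom_name == "SG"] <- "S"
  at$is_heavy <- TRUE
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  co <- do.call(rbind, xyz)
  rownames(co) <- NULL

  topo <- topology_config(
    stats::setNames(ifelse(ring == 1, "HC1", "HC2"), chains),
    extracellular_ranges = spec$extracellular_ranges
  )
  list(frame = new_frame(at, co), topology = topo, spec = spec)
}

#' Specification of planted trajectory features
#'
#' @param planted_scs Data frame with columns `chain_u`, `res_seq_u`,
#'   `chain_v`, `res_seq_v`, `support` (target supporting-contact count,
#'   7-9) and `occupancy` (target fraction of frames present, in `[0, 1]`).
#' @param planted_disulfides Data frame with `chain_u`, `res_seq_u`,
#'   `chain_v`, `res_seq_v`, `target_A` (SG-SG distance in close mode,
#'   default 2.05).
#' @param psi_coupling `NULL`, or a list with `residues` (data frame
#'   `chain`, `res_seq`), `window` (a [psi_window()]), `fidelity` (in
#'   `[0.5, 1]`; 0.5 = independence), `sense` (`"anti"`: psi enters the
#'   window when the coupled stabilization center is absent; `"pro"`: when
#'   present) and `coupled_pair` (row index into `planted_scs`).
#' @param n_frames Number of frames (default 100).
#' @param mode `"deterministic"` (exact per-pair presence counts,
#'   `round(occupancy * n_frames)`) or `"bernoulli"` (independent draws).
#' @param disulfide_mode `"close"` (SG pairs held at `target_A`) or
#'   `"open"` (SG pairs stretched to 5 A, beyond both the bond cutoff and
#'   the contact cutoff).
#' @param jitter_sd Gaussian coordinate jitter per frame in Angstrom
#'   (default 0.05; small against the >= 0.5 A guard bands on either side of
#'   every planted contact state).
#' @param seed Integer seed; the whole trajectory is deterministic given it.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(planted_scs = NULL, planted_disulfides = NULL,
                       psi_coupling = NULL, n_frames = 100,
                       mode = c("deterministic", "bernoulli"),
                       disulfide_mode = c("close", "open"),
                       jitter_sd = 0.05, seed = 1) {
  mode <- match.arg(mode)
  disulfide_mode <- match.arg(disulfide_mode)
  if (n_frames < 1) stop_sctraj("sctraj_spec", "n_frames must be >= 1")
  if (!is.null(planted_scs)) {
    if (any(planted_scs$support < 1 | planted_scs$support > 9))
      stop_sctraj("sctraj_spec", "planted support must be in 1..9")
    if (any(planted_scs$occupancy < 0 | planted_scs$occupancy > 1))
      stop_sctraj("sctraj_spec", "occupancy must be in [0, 1]")
  }
  if (!is.null(psi_coupling)) {
    if (psi_coupling$fidelity < 0.5 || psi_coupling$fidelity > 1)
      stop_sctraj("sctraj_spec", "fidelity must be in [0.5, 1]")
    if (!psi_coupling$sense %in% c("anti", "pro"))
      stop_sctraj("sctraj_spec", "sense must be 'anti' or 'pro'")
  }
  structure(list(planted_scs = planted_scs,
                 planted_disulfides = planted_disulfides,
                 psi_coupling = psi_coupling,
                 n_frames = as.integer(n_frames), mode = mode,
                 disulfide_mode = disulfide_mode,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Default planted features for the toy gap-junction assembly
#'
#' The study conditions emulated by default: a trans-interface stabilization
#' center between the facing subunits D and G at the EL1 docking residues
#' (55-56), an intra-subunit EL1-EL2 stabilization center at the central
#' cysteine pair (54-198), an intra-EL1 stabilization center (52-65), the
#' three disulfide bridges 54-198, 61-192, 65-187 in every chain, and an
#' anti-sense psi coupling of residue 193 in the two interface subunits to
#' the trans-interface stabilization center.
#'
#' @param assembly Output of [build_toy_assembly()].
#' @param n_frames,mode,disulfide_mode,jitter_sd,seed Passed to
#'   [plant_spec()].
#' @param fidelity Psi-coupling fidelity (default 0.9).
#' @return A `plant_spec`.
#' @export
default_plant_spec <- function(assembly, n_frames = 100,
                               mode = "deterministic",
                               disulfide_mode = "close", jitter_sd = 0.05,
                               fidelity = 0.9, seed = 1) {
  topo <- assembly$topology
  chains <- names(topo$hemichannel_of)
  ring1 <- chains[topo$hemichannel_of == "HC1"]
  ring2 <- chains[topo$hemichannel_of == "HC2"]
  c_pre <- if ("D" %in% ring1) "D" else ring1[1]
  c_post <- ring2[1]
  c_intra <- ring1[1]
  scs <- data.frame(
    chain_u = c(c_pre, c_pre, c_intra),
    res_seq_u = c(55, 54, 52),
    chain_v = c(c_post, c_pre, c_intra),
    res_seq_v = c(56, 198, 65),
    support = c(9, 8, 7),
    occupancy = c(0.9, 0.6, 0.3),
    stringsAsFactors = FALSE
  )
  ss <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(chain_u = ch, res_seq_u = c(54, 61, 65),
               chain_v = ch, res_seq_v = c(198, 192, 187),
               target_A = 2.05, stringsAsFactors = FALSE)
  }))
  coupling <- list(
    residues = data.frame(chain = c(c_pre, c_post), res_seq = 193,
                          stringsAsFactors = FALSE),
    window = psi_window(-45, 0), fidelity = fidelity, sense = "anti",
    coupled_pair = 1L
  )
  plant_spec(planted_scs = scs, planted_disulfides = ss,
             psi_coupling = coupling, n_frames = n_frames, mode = mode,
             disulfide_mode = disulfide_mode, jitter_sd = jitter_sd,
             seed = seed)
}

# chain-position triplet around a residue row of a residue table
assembly_triplet <- function(res, chain, res_seq) {
  row <- which(res$chain == chain & res$res_seq == res_seq & res$icode == "")
  if (length(row) != 1)
    stop_sctraj("sctraj_spec", "planted residue %s:%d not in assembly",
                chain, res_seq)
  triplet_uids(res, row)
}

# exact-count presence draw
draw_presence <- function(n, occ, mode) {
  if (mode == "deterministic") {
    k <- round(occ * n)
    pres <- rep(FALSE, n)
    if (k > 0) pres[sample.int(n, k)] <- TRUE
    pres
  } else {
    stats::runif(n) < occ
  }
}

# flip a target logical vector so that it matches with probability `fidelity`
apply_fidelity <- function(target, fidelity, mode) {
  n <- length(target)
  if (mode == "deterministic") {
    k <- round((1 - fidelity) * n)
    flip <- rep(FALSE, n)
    if (k > 0) flip[sample.int(n, k)] <- TRUE
  } else {
    flip <- stats::runif(n) < (1 - fidelity)
  }
  xor(target, flip)
}

#' Generate a trajectory with planted ground truth
#'
#' Rolls `n_frames` frames of the toy assembly.  Each planted stabilization
#' center is present or absent per frame (matching its target occupancy
#' exactly in deterministic mode); present frames realize exactly `support`
#' supporting contacts through bridge atoms at isolated interaction sites,
#' absent frames displace the u-side bridge atoms far beyond the contact
#' cutoff.  Disulfide SG pairs are held at their target distance ("close")
#' or stretched to 5 A ("open").  The psi angle of the designated residues
#' is placed inside its window (uniform in [-38, -8] degrees) or outside
#' (uniform in [152, 177]) according to the coupling sense and fidelity,
#' margins that jitter cannot bridge.
#' Gaussian jitter is added to every coordinate in every frame.
#'
#' @param assembly Output of [build_toy_assembly()].
#' @param pspec A [plant_spec()].
#' @return A list with `trajectory` (an `sc_trajectory`) and `truth`
#'   (frame-level ground truth: planted pair table with class labels and
#'   realized occupancies, presence matrix, psi window-state vector,
#'   disulfide table, and the full spec echo).
#' @export
plant_and_roll <- function(assembly, pspec) {
  at <- assembly$frame$atoms
  base <- assembly$frame$xyz
  res <- frame_residues(assembly$frame)
  topo <- assembly$topology
  n <- pspec$n_frames
  scs <- pspec$planted_scs
  n_sc <- if (is.null(scs)) 0 else nrow(scs)

  if (n_sc > 0) {
    keys <- pair_key(residue_uid(scs$chain_u, scs$res_seq_u),
                     residue_uid(scs$chain_v, scs$res_seq_v))
    if (anyDuplicated(keys))
      stop_sctraj("sctraj_spec",
                  "conflicting placements: duplicated planted pair %s",
                  keys[duplicated(keys)][1])
  }

  site_x0 <- assembly$spec$ring_radius_A + 60
  site_step <- 14
  site_count <- 0
  next_site <- function() {
    site_count <<- site_count + 1
    c(site_x0 + site_step * (site_count - 1), 0, 0)
  }

  extra_atoms <- list()
  extra_xyz <- list()
  # for each planted SC: indices (into the extra-atom list) of its u-side
  # bridge atoms, to displace in absent frames
  u_side_of <- vector("list", n_sc)
  support_sets <- vector("list", n_sc)

  add_atom <- function(uid, name, element, pos) {
    row <- res[match(uid, res$uid), ]
    extra_atoms[[length(extra_atoms) + 1]] <<- data.frame(
      atom_name = name, alt_loc = "", res_name = row$res_name,
      chain = row$chain, res_seq = row$res_seq, icode = row$icode,
      element = element, is_heavy = TRUE, serial = NA_integer_,
      stringsAsFactors = FALSE)
    extra_xyz[[length(extra_xyz) + 1]] <<- pos
    length(extra_atoms)
  }

  if (n_sc > 0) {
    for (p in seq_len(n_sc)) {
      tu <- assembly_triplet(res, scs$chain_u[p], scs$res_seq_u[p])
      tv <- assembly_triplet(res, scs$chain_v[p], scs$res_seq_v[p])
      uid_u <- residue_uid(scs$chain_u[p], scs$res_seq_u[p])
      uid_v <- residue_uid(scs$chain_v[p], scs$res_seq_v[p])
      grid <- expand.grid(u = tu, v = tv, stringsAsFactors = FALSE)
      # order: central pair first, then by triplet distance from the centre
      du <- abs(match(grid$u, tu) - match(uid_u, tu))
      dv <- abs(match(grid$v, tv) - match(uid_v, tv))
      grid <- grid[order(du + dv, du, dv), , drop = FALSE]
      if (scs$support[p] > nrow(grid))
        stop_sctraj("sctraj_spec",
                    "support %d exceeds the %d available triplet pairs",
                    scs$support[p], nrow(grid))
      sel <- grid[seq_len(scs$support[p]), , drop = FALSE]
      support_sets[[p]] <- sel
      uu <- integer(nrow(sel))
      for (s in seq_len(nrow(sel))) {
        site <- next_site()
        uu[s] <- add_atom(sel$u[s], sprintf("X%d%d", p, s), "C",
                          site + c(-1, 0, 0))
        add_atom(sel$v[s], sprintf("Y%d%d", p, s), "C",
                 site + c(1, 0, 0))
      }
      u_side_of[[p]] <- uu
    }
  }

  # disulfides: relocate the SG atoms of each planted pair to a shared site
  ss <- pspec$planted_disulfides
  sg_rows <- function(chain, res_seq) {
    which(at$chain == chain & at$res_seq == res_seq &
            at$atom_name == "SG")
  }
  if (!is.null(ss)) {
    half <- if (pspec$disulfide_mode == "close") ss$target_A / 2
            else rep(2.5, nrow(ss))
    for (q in seq_len(nrow(ss))) {
      i <- sg_rows(ss$chain_u[q], ss$res_seq_u[q])
      j <- sg_rows(ss$chain_v[q], ss$res_seq_v[q])
      if (length(i) != 1 || length(j) != 1)
        stop_sctraj("sctraj_spec",
                    "disulfide residue %s:%d or %s:%d lacks an SG atom",
                    ss$chain_u[q], ss$res_seq_u[q],
                    ss$chain_v[q], ss$res_seq_v[q])
      site <- next_site()
      base[i, ] <- site + c(-half[q], 0, 0)
      base[j, ] <- site + c(half[q], 0, 0)
    }
  }

  # assemble the full atom table (base + bridge atoms), chain/residue sorted
  if (length(extra_atoms)) {
    extra <- do.call(rbind, extra_atoms)
    n_base <- nrow(at)
    at_all <- rbind(at[, names(extra)], extra)
    xyz_all <- rbind(base, do.call(rbind, extra_xyz))
    perm <- order(at_all$chain, at_all$res_seq, at_all$icode)
    at_all <- at_all[perm, , drop = FALSE]
    xyz_all <- xyz_all[perm, , drop = FALSE]
    # where each extra atom ended up after the sort
    extra_pos <- match(n_base + seq_len(nrow(extra)), perm)
  } else {
    at_all <- at
    xyz_all <- base
    extra_pos <- integer(0)
  }
  at_all$serial <- seq_len(nrow(at_all))
  rownames(at_all) <- NULL

  psi <- pspec$psi_coupling
  psi_idx <- NULL
  if (!is.null(psi)) {
    if (is.null(scs) || psi$coupled_pair > n_sc)
      stop_sctraj("sctraj_spec", "psi_coupling$coupled_pair out of range")
    psi_idx <- lapply(seq_len(nrow(psi$residues)), function(r) {
      ch <- psi$residues$chain[r]; rs <- psi$residues$res_seq[r]
      find1 <- function(rs2, nm) {
        i <- which(at_all$chain == ch & at_all$res_seq == rs2 &
                     at_all$atom_name == nm)
        if (length(i) != 1)
          stop_sctraj("sctraj_spec",
                      "psi residue %s:%d needs atom %s of residue %d",
                      ch, rs, nm, rs2)
        i
      }
      list(N = find1(rs, "N"), CA = find1(rs, "CA"), C = find1(rs, "C"),
           N_next = find1(rs + 1, "N"),
           ca_pos = xyz_all[which(at_all$chain == ch &
                                    at_all$res_seq == rs &
                                    at_all$atom_name == "CA"), ])
    })
  }

  result <- with_seed(pspec$seed, {
    presence <- matrix(FALSE, n, max(n_sc, 0))
    if (n_sc > 0)
      for (p in seq_len(n_sc))
        presence[, p] <- draw_presence(n, scs$occupancy[p], pspec$mode)

    window_state <- NULL
    psi_targets <- NULL
    if (!is.null(psi)) {
      s_cpl <- presence[, psi$coupled_pair]
      target <- if (psi$sense == "anti") !s_cpl else s_cpl
      window_state <- apply_fidelity(target, psi$fidelity, pspec$mode)
      psi_targets <- ifelse(window_state,
                            stats::runif(n, -38, -8),
                            stats::runif(n, 152, 177))
    }

    coords <- array(NA_real_, dim = c(nrow(at_all), 3, n))
    for (f in seq_len(n)) {
      fx <- xyz_all
      if (n_sc > 0) {
        for (p in seq_len(n_sc)) {
          if (!presence[f, p]) {
            rows <- extra_pos[u_side_of[[p]]]
            fx[rows, 2] <- fx[rows, 2] + 300
          }
        }
      }
      if (!is.null(psi)) {
        a <- psi_targets[f] * pi / 180
        for (pi_ in psi_idx) {
          # long lever arms (scaled canonical frame) keep the realized
          # dihedral within ~1 degree of the target under coordinate jitter
          ca <- pi_$ca_pos
          fx[pi_$N, ] <- ca + c(-1.5, 4.2, 0)
          fx[pi_$CA, ] <- ca
          fx[pi_$C, ] <- ca + c(4.5, 0, 0)
          fx[pi_$N_next, ] <- ca + c(4.5 + 1.4, 4 * cos(a), 4 * sin(a))
        }
      }
      coords[, , f] <- fx +
        stats::rnorm(length(fx), sd = pspec$jitter_sd)
    }
    list(presence = presence, window_state = window_state,
         psi_targets = psi_targets, coords = coords)
  })

  traj <- new_trajectory(at_all, result$coords, frame_interval_ps = 10)
  validate_trajectory(traj)

  truth_pairs <- NULL
  if (n_sc > 0) {
    truth_pairs <- scs
    truth_pairs$key <- pair_key(
      residue_uid(scs$chain_u, scs$res_seq_u),
      residue_uid(scs$chain_v, scs$res_seq_v))
    truth_pairs$realized_occupancy <- colMeans(result$presence)
    # class by construction (ring membership / loop intervals)
    hc <- topo$hemichannel_of
    iu <- extracellular_interval(scs$res_seq_u, topo)
    iv <- extracellular_interval(scs$res_seq_v, topo)
    cls <- character(n_sc)
    for (p in seq_len(n_sc)) {
      if (hc[scs$chain_u[p]] != hc[scs$chain_v[p]]) cls[p] <- "TRANS_GJ"
      else if (scs$chain_u[p] != scs$chain_v[p])
        cls[p] <- "INTER_SUBUNIT_INTRA_HC"
      else if (iu[p] > 0 && iv[p] > 0 && iu[p] != iv[p])
        cls[p] <- "INTRA_SUBUNIT_INTER_LOOP"
      else if (iu[p] > 0 && iv[p] > 0) cls[p] <- "INTRA_LOOP"
      else cls[p] <- "OTHER"
    }
    truth_pairs$class <- cls
    colnames(result$presence) <- truth_pairs$key
  }

  truth <- structure(list(
    pairs = truth_pairs,
    presence = result$presence,
    window_state = result$window_state,
    psi_targets = result$psi_targets,
    disulfides = ss,
    disulfide_mode = pspec$disulfide_mode,
    plant_spec = pspec,
    assembly_spec = assembly$spec,
    seed = pspec$seed
  ), class = "sc_ground_truth")

  list(trajectory = traj, truth = truth)
}

#' Simulate coupled presence / psi series without geometry
#'
#' The statistical arm of the generator: draws a stabilization-center
#' presence vector and a psi series coupled to it with the given fidelity
#' and sense, exactly as [plant_and_roll()] does internally, but without
#' building coordinates.  Used to calibrate the association statistic.
#'
#' @param n_frames Number of frames.
#' @param occupancy Stabilization-center occupancy.
#' @param fidelity Coupling fidelity in `[0.5, 1]`; 0.5 = independence.
#' @param sense `"anti"` or `"pro"`.
#' @param window A [psi_window()].
#' @param seed Integer seed.
#' @param mode `"bernoulli"` (default) or `"deterministic"`.
#' @return List with `presence`, `window_state` and `psi` (degrees).
#' @export
simulate_coupled_series <- function(n_frames, occupancy = 0.5,
                                    fidelity = 0.5,
                                    sense = c("anti", "pro"),
                                    window = psi_window(), seed = 1,
                                    mode = c("bernoulli",
                                             "deterministic")) {
  sense <- match.arg(sense)
  mode <- match.arg(mode)
  with_seed(seed, {
    presence <- draw_presence(n_frames, occupancy, mode)
    target <- if (sense == "anti") !presence else presence
    w <- apply_fidelity(target, fidelity, mode)
    lo <- window$lo_deg; hi <- window$hi_deg
    pad <- 0.1 * (hi - lo)
    psi <- ifelse(w, stats::runif(n_frames, lo + pad, hi - pad),
                  stats::runif(n_frames, 155, 180))
    list(presence = presence, window_state = w, psi = psi)
  })
}

#' Simulate a connexin-family-like extracellular-loop alignment
#'
#' Builds a synthetic multiple alignment whose reference row is the
#' concatenated Cx43 EL1 + EL2 sequence and whose other rows are seeded
#' mutants: each non-reference row substitutes a random residue with
#' probability `sub_rate` per column and opens occasional single-column
#' gaps.  A stand-in for a real connexin family alignment, for exercising
#' the conservation machinery only.
#'
#' @param n_seqs Number of sequences including the reference (default 8).
#' @param sub_rate Per-column substitution probability (default 0.25).
#' @param gap_rate Per-column gap probability in non-reference rows
#'   (default 0.03).
#' @param seed Integer seed.
#' @return An `msa_alignment` with reference `Cx43`.
#' @export
simulate_el_alignment <- function(n_seqs = 8, sub_rate = 0.25,
                                  gap_rate = 0.03, seed = 1) {
  if (n_seqs < 2) stop_sctraj("sctraj_spec", "n_seqs must be >= 2")
  els <- cx43_el_sequences()
  ref <- c(els$EL1$aa, els$EL2$aa)
  aa <- names(AA_THREE)
  with_seed(seed, {
    rows <- list(Cx43 = paste(ref, collapse = ""))
    for (k in seq_len(n_seqs - 1)) {
      s <- ref
      mut <- stats::runif(length(s)) < sub_rate
      s[mut] <- sample(aa, sum(mut), replace = TRUE)
      gap <- stats::runif(length(s)) < gap_rate
      s[gap] <- "-"
      rows[[sprintf("CxSyn%02d", k)]] <- paste(s, collapse = "")
    }
    new_alignment(unlist(rows), reference_id = "Cx43")
  })
}

#' Write an alignment as aligned FASTA
#' @param aln An `msa_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}
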