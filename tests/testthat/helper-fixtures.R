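# Shared fixtures and independent oracles for the test suite.
#
# The brute-force functions below deliberately re-derive contacts and
# stabilization centers from first principles (all-pairs loops over
# residue_min_distance) so they are independent of the cell-list engine
# they are used to check.

# Build a frame from a flat atom table (chain, res_seq, res_name, atom_name,
# element, x, y, z; optional icode).
make_frame <- function(df) {
  df$icode <- df$icode %||% ""
  at <- data.frame(
    atom_name = df$atom_name, alt_loc = "", res_name = df$res_name,
    chain = df$chain, res_seq = as.integer(df$res_seq), icode = df$icode,
    element = df$element,
    is_heavy = !(toupper(df$element) %in% c("H", "D")),
    stringsAsFactors = FALSE
  )
  o <- order(at$chain, at$res_seq, at$icode)
  at <- at[o, , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  sctraj:::new_frame(at, as.matrix(df[o, c("x", "y", "z")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a single frame into a 1..n frame trajectory (replicated coordinates).
frame_to_traj <- function(frame, n = 1, frame_interval_ps = 10) {
  co <- array(rep(frame$xyz, n), dim = c(nrow(frame$atoms), 3, n))
  sctraj:::new_trajectory(frame$atoms, co, frame_interval_ps)
}

# Independent O(n^2) contact oracle.
brute_force_contacts <- function(frame, vdw = default_vdw_table(),
                                 cp = contact_params()) {
  res <- sctraj:::frame_residues(frame)
  at <- frame$atoms
  out <- list()
  for (i in seq_len(nrow(res) - 1)) {
    for (j in (i + 1):nrow(res)) {
      ii <- res$idx[[i]]; jj <- res$idx[[j]]
      r <- residue_min_distance(frame$xyz[ii, , drop = FALSE],
                                frame$xyz[jj, , drop = FALSE],
                                at$element[ii], at$element[jj], vdw, cp)
      if (r$in_contact) {
        lr <- res$chain[i] != res$chain[j] ||
          abs(res$res_seq[i] - res$res_seq[j]) >= cp$min_seq_separation
        out[[length(out) + 1]] <- data.frame(
          uid_u = res$uid[i], uid_v = res$uid[j],
          min_dist_A = r$min_dist_A, is_long_range = lr,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(uid_u = character(0), uid_v = character(0),
                      min_dist_A = numeric(0), is_long_range = logical(0)))
  do.call(rbind, out)
}

# Independent stabilization-center oracle built on the brute-force contacts.
brute_force_scs <- function(frame, vdw = default_vdw_table(),
                            cp = contact_params(), sp = sc_params()) {
  res <- sctraj:::frame_residues(frame)
  contacts <- brute_force_contacts(frame, vdw, cp)
  keys <- sctraj:::pair_key(contacts$uid_u, contacts$uid_v)
  lr <- contacts[contacts$is_long_range, , drop = FALSE]
  out <- list()
  trip <- function(uid) {
    row <- match(uid, res$uid)
    sel <- res$chain == res$chain[row] &
      abs(res$chain_pos - res$chain_pos[row]) <= 1
    res$uid[sel]
  }
  for (k in seq_len(nrow(lr))) {
    tu <- trip(lr$uid_u[k]); tv <- trip(lr$uid_v[k])
    grid <- sctraj:::pair_key(rep(tu, times = length(tv)),
                              rep(tv, each = length(tu)))
    supp <- sum(grid %in% keys)
    thr <- if (sp$truncation_rule == "proportional")
      ceiling(sp$support_threshold * length(grid) / 9)
    else sp$support_threshold
    if (supp >= thr)
      out[[length(out) + 1]] <- data.frame(
        uid_u = lr$uid_u[k], uid_v = lr$uid_v[k], support_count = supp,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(uid_u = character(0), uid_v = character(0),
                      support_count = integer(0)))
  do.call(rbind, out)
}

# Random multi-chain frame: n_res residues with 1-3 carbon/nitrogen atoms
# scattered in a cubic box (dense enough for plenty of contacts).
random_frame <- function(n_res, seed, box = 22) {
  set.seed(seed)
  rows <- list()
  chains <- c("A", "B")
  for (r in seq_len(n_res)) {
    ch <- chains[1 + (r > n_res / 2)]
    rs <- if (ch == "A") r else r - floor(n_res / 2)
    centre <- runif(3, 0, box)
    n_at <- sample(1:3, 1)
    for (a in seq_len(n_at)) {
      p <- centre + runif(3, -0.8, 0.8)
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, res_seq = rs, res_name = "ALA",
        atom_name = c("CA", "CB", "N")[a],
        element = c("C", "C", "N")[a],
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  make_frame(do.call(rbind, rows))
}

# Minimal sc_series object for filter-semantics tests.
make_series <- function(pairs, presence) {
  pairs$uid_u <- sctraj:::residue_uid(pairs$chain_u, pairs$res_seq_u)
  pairs$uid_v <- sctraj:::residue_uid(pairs$chain_v, pairs$res_seq_v)
  pairs$occupancy <- colMeans(presence)
  structure(list(pairs = pairs, presence = presence,
                 frame_interval_ps = 10), class = "sc_series")
}

default_asm <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_toy_assembly(assembly_spec(seed = 1))
    val
  }
})

# random rigid transform (proper rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = runif(3, -20, 20))
}

# ideal planar trans peptide: CA(1), C(1), N(2), CA(2) anti across the
# C-N bond, replicated over frames
trans_peptide_traj <- function(n_frames = 3) {
  rows <- data.frame(
    chain = "A", res_seq = c(1, 1, 1, 2, 2, 2),
    res_name = c("ALA", "ALA", "ALA", "PRO", "PRO", "PRO"),
    atom_name = c("N", "CA", "C", "N", "CA", "C"),
    element = c("N", "C", "C", "N", "C", "C"),
    x = c(-1.2, 0, 1.5, 2.2, 3.7, 4.4),
    y = c(-0.8, 0, 0, 1.1, 1.1, 2.3),
    z = 0)
  frame_to_traj(make_frame(rows), n_frames)
}
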