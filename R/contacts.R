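# Residue-residue contacts under the van der Waals + margin criterion.
#
# Two residues are in contact when at least one pair of their (heavy) atoms
# is closer than vdW(a) + vdW(b) + margin, with strict inequality.  A contact
# is long-range when the residues sit on different chains, or on the same
# chain at sequence separation >= min_seq_separation.

#' Contact detection parameters
#'
#' @param margin_A Margin added to the sum of van der Waals radii (Angstrom,
#'   default 1.0).
#' @param min_seq_separation Minimum intra-chain residue separation for a
#'   contact to count as long-range (default 10).  All inter-chain pairs are
#'   long-range.
#' @param use_heavy_only Use heavy atoms only (default TRUE); hydrogens then
#'   never affect any contact.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(margin_A = 1.0, min_seq_separation = 10,
                           use_heavy_only = TRUE) {
  if (margin_A < 0) stop_sctraj("sctraj_invalid", "margin_A must be >= 0")
  if (min_seq_separation < 1)
    stop_sctraj("sctraj_invalid", "min_seq_separation must be >= 1")
  structure(list(margin_A = margin_A,
                 min_seq_separation = as.integer(min_seq_separation),
                 use_heavy_only = isTRUE(use_heavy_only)),
            class = "contact_params")
}

#' Stabilization-center parameters
#'
#' A long-range contact (u, v) is a stabilization center when the contacting
#' pairs among the 3x3 sequence-neighbour triplets centred on u and v number
#' at least `support_threshold` (of 9 candidates).  When a triplet is cut by
#' a chain terminus the candidate count drops below 9; the `proportional`
#' truncation rule then requires `ceiling(support_threshold * n_pairs / 9)`
#' contacts, while `strict` keeps the absolute threshold (making terminal
#' stabilization centers rarer).
#'
#' @param support_threshold Required contacting pairs among the 9 triplet
#'   pairs (default 7; must be in 1..9).
#' @param truncation_rule `"proportional"` (default) or `"strict"`.
#' @return An object of class `sc_params`.
#' @export
sc_params <- function(support_threshold = 7,
                      truncation_rule = c("proportional", "strict")) {
  if (support_threshold < 1 || support_threshold > 9)
    stop_sctraj("sctraj_invalid", "support_threshold must be in 1..9")
  structure(list(support_threshold = as.integer(support_threshold),
                 truncation_rule = match.arg(truncation_rule)),
            class = "sc_params")
}

#' Minimum inter-residue atom distance and contact state
#'
#' @param r1,r2 Matrices of atom coordinates (rows are atoms, columns x/y/z).
#' @param elem1,elem2 Element symbols for the rows of `r1`, `r2`.
#' @param vdw A [default_vdw_table()] (or compatible) radius table.
#' @param params [contact_params()].
#' @return A list with `min_dist_A` (minimum raw atom distance) and
#'   `in_contact` (TRUE iff some atom pair is closer than the sum of its
#'   van der Waals radii plus the margin, strictly).
#' @export
residue_min_distance <- function(r1, r2, elem1, elem2,
                                 vdw = default_vdw_table(),
                                 params = contact_params()) {
  r1 <- rbind(r1); r2 <- rbind(r2)
  if (params$use_heavy_only) {
    h1 <- !(toupper(elem1) %in% c("H", "D"))
    h2 <- !(toupper(elem2) %in% c("H", "D"))
    r1 <- r1[h1, , drop = FALSE]; elem1 <- elem1[h1]
    r2 <- r2[h2, , drop = FALSE]; elem2 <- elem2[h2]
  }
  if (nrow(r1) == 0 || nrow(r2) == 0)
    stop_sctraj("sctraj_degenerate",
                "residue has no atoms after heavy-atom filtering")
  d2 <- outer(rowSums(r1^2), rowSums(r2^2), "+") - 2 * (r1 %*% t(r2))
  d <- sqrt(pmax(d2, 0))
  cutoff <- outer(vdw_radius(vdw, elem1), vdw_radius(vdw, elem2), "+") +
    params$margin_A
  list(min_dist_A = min(d), in_contact = any(d < cutoff))
}

# Core contact engine for a frame, accelerated by an atom-level cell list:
# atoms are binned into cubic cells of side 2*max(radius) + margin, so every
# atom pair that can possibly satisfy its per-pair cutoff lies in the same
# or an adjacent cell.  Atom pairs from neighbouring cells are evaluated
# exactly and aggregated to residue pairs.  The result is independent of the
# binning and identical to a brute-force all-pairs scan (asserted against an
# independent oracle in the test suite).
frame_contact_table <- function(frame, vdw = default_vdw_table(),
                                params = contact_params()) {
  at <- frame$atoms
  xyz <- frame$xyz
  if (params$use_heavy_only) {
    keep <- at$is_heavy
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
  }
  uid <- residue_uid(at$chain, at$res_seq, at$icode)
  res <- frame_residues(new_frame(at, xyz))
  rad <- vdw_radius(vdw, at$element)
  rid <- match(uid, res$uid)
  n_atom <- nrow(xyz)

  empty <- data.frame(i = integer(0), j = integer(0),
                      min_dist_A = numeric(0), in_contact = logical(0))
  if (n_atom < 2) return(empty)

  L <- 2 * max(rad) + params$margin_A
  cell <- floor(xyz / L)
  ckey <- paste(cell[, 1], cell[, 2], cell[, 3])
  cells <- unique(ckey)
  cid <- match(ckey, cells)
  members <- split(seq_len(n_atom), cid)
  ccoord <- cell[match(cells, ckey), , drop = FALSE]

  # half of the 26 neighbour offsets (lexicographically positive), so each
  # cell pair is visited once; same-cell pairs handled separately
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 |
                 (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]

  ai_list <- list(); bi_list <- list()
  # within-cell pairs
  for (m in members) {
    n <- length(m)
    if (n > 1) {
      ai_list[[length(ai_list) + 1]] <-
        m[rep(seq_len(n - 1), times = (n - 1):1)]
      bi_list[[length(bi_list) + 1]] <-
        m[unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))]
    }
  }
  # cross-cell pairs
  for (o in seq_len(nrow(offs))) {
    nb_key <- paste(ccoord[, 1] + offs[o, 1], ccoord[, 2] + offs[o, 2],
                    ccoord[, 3] + offs[o, 3])
    nb <- match(nb_key, cells)
    has <- which(!is.na(nb))
    for (c1 in has) {
      A <- members[[c1]]; B <- members[[nb[c1]]]
      ai_list[[length(ai_list) + 1]] <- rep(A, times = length(B))
      bi_list[[length(bi_list) + 1]] <- rep(B, each = length(A))
    }
  }
  if (length(ai_list) == 0) return(empty)
  ai <- unlist(ai_list, use.names = FALSE)
  bi <- unlist(bi_list, use.names = FALSE)

  keep <- rid[ai] != rid[bi]
  ai <- ai[keep]; bi <- bi[keep]
  if (length(ai) == 0) return(empty)

  d <- sqrt(rowSums((xyz[ai, , drop = FALSE] -
                       xyz[bi, , drop = FALSE])^2))
  within <- d < L
  ai <- ai[within]; bi <- bi[within]; d <- d[within]
  if (length(ai) == 0) return(empty)
  # adjusted distance: below margin_A means the atom pair is in contact
  adj <- d - rad[ai] - rad[bi]

  r1 <- pmin(rid[ai], rid[bi])
  r2 <- pmax(rid[ai], rid[bi])
  g <- (r1 - 1) * nrow(res) + r2
  o1 <- order(g, d)
  first_d <- o1[!duplicated(g[o1])]
  o2 <- order(g, adj)
  first_a <- o2[!duplicated(g[o2])]
  data.frame(i = r1[first_d], j = r2[first_d],
             min_dist_A = d[first_d],
             in_contact = adj[first_a] < params$margin_A)
}

contact_pairs_df <- function(res, tab, params) {
  u <- res[tab$i, ]; v <- res[tab$j, ]
  swap <- canonical_pair_order(u$chain, u$res_seq, u$icode,
                               v$chain, v$res_seq, v$icode)
  a <- ifelse(swap, tab$j, tab$i)
  b <- ifelse(swap, tab$i, tab$j)
  u <- res[a, ]; v <- res[b, ]
  lr <- (u$chain != v$chain) |
    (abs(u$res_seq - v$res_seq) >= params$min_seq_separation)
  out <- data.frame(
    chain_u = u$chain, res_seq_u = u$res_seq, icode_u = u$icode,
    res_name_u = u$res_name,
    chain_v = v$chain, res_seq_v = v$res_seq, icode_v = v$icode,
    res_name_v = v$res_name,
    min_dist_A = tab$min_dist_A, is_long_range = lr,
    stringsAsFactors = FALSE
  )
  out$uid_u <- residue_uid(out$chain_u, out$res_seq_u, out$icode_u)
  out$uid_v <- residue_uid(out$chain_v, out$res_seq_v, out$icode_v)
  rownames(out) <- NULL
  out
}

#' Find all residue-residue contacts in a frame
#'
#' @inheritParams residue_min_distance
#' @param frame A frame from [get_frame()].
#' @return A data frame with one row per unordered contacting residue pair
#'   (canonically sorted), carrying the minimum atom distance and the
#'   long-range flag.
#' @export
find_contacts <- function(frame, vdw = default_vdw_table(),
                          params = contact_params()) {
  tab <- frame_contact_table(frame, vdw, params)
  res <- frame_residues(frame)
  tab <- tab[tab$in_contact, , drop = FALSE]
  out <- contact_pairs_df(res, tab, params)
  out[order(out$uid_u, out$uid_v), , drop = FALSE]
}

# Triplet of chain-position neighbours (pos-1, pos, pos+1) clipped at termini.
triplet_uids <- function(res, row) {
  ch <- res$chain[row]
  pos <- res$chain_pos[row]
  sel <- res$chain == ch & res$chain_pos >= pos - 1 & res$chain_pos <= pos + 1
  res$uid[sel]
}

#' Find stabilization centers in a frame
#'
#' A stabilization center is a long-range contact (u, v) whose sequence
#' neighbourhoods also interact densely: among the candidate pairs
#' `(u', v')` with `u'` in the triplet `u-1, u, u+1` (clipped at chain
#' termini) and `v'` in the triplet around `v`, at least
#' `support_threshold` pairs (rule-adjusted at termini, see [sc_params()])
#' must themselves be in contact.
#'
#' @inheritParams find_contacts
#' @param cparams [contact_params()].
#' @param sparams [sc_params()].
#' @return A data frame of stabilization-center pairs with `support_count`
#'   and `min_dist_A`, a subset of the long-range rows of [find_contacts()].
#' @export
find_stabilization_centers <- function(frame, vdw = default_vdw_table(),
                                       cparams = contact_params(),
                                       sparams = sc_params()) {
  res <- frame_residues(frame)
  tab <- frame_contact_table(frame, vdw, cparams)
  tab <- tab[tab$in_contact, , drop = FALSE]
  contacts <- contact_pairs_df(res, tab, cparams)
  keys <- pair_key(contacts$uid_u, contacts$uid_v)

  lr <- which(contacts$is_long_range)
  if (length(lr) == 0) return(contacts[integer(0), , drop = FALSE])

  row_of <- match(c(contacts$uid_u[lr], contacts$uid_v[lr]), res$uid)
  row_u <- row_of[seq_along(lr)]
  row_v <- row_of[length(lr) + seq_along(lr)]

  support <- integer(length(lr))
  n_cand <- integer(length(lr))
  for (k in seq_along(lr)) {
    tu <- triplet_uids(res, row_u[k])
    tv <- triplet_uids(res, row_v[k])
    grid <- pair_key(rep(tu, times = length(tv)), rep(tv, each = length(tu)))
    n_cand[k] <- length(grid)
    support[k] <- sum(grid %in% keys)
  }
  thr <- if (sparams$truncation_rule == "proportional") {
    ceiling(sparams$support_threshold * n_cand / 9)
  } else {
    rep(sparams$support_threshold, length(lr))
  }
  keep <- lr[support >= thr]
  out <- contacts[keep, , drop = FALSE]
  out$support_count <- support[support >= thr]
  out$n_support_candidates <- n_cand[support >= thr]
  out[order(out$uid_u, out$uid_v), , drop = FALSE]
}

#' Detect disulfide bonds in a frame
#'
#' Cysteine pairs whose SG-SG distance falls below the cutoff, with each SG
#' matched to at most one partner by greedy ascending-distance matching.
#' Cysteines lacking an SG atom are skipped with a warning.
#'
#' @param frame A frame.
#' @param sg_cutoff_A SG-SG distance cutoff in Angstrom (default 2.5).
#' @return Data frame of bonded cysteine pairs (canonically ordered) with
#'   their SG-SG distance.
#' @export
detect_disulfides <- function(frame, sg_cutoff_A = 2.5) {
  at <- frame$atoms
  cys <- which(at$res_name == "CYS" & at$atom_name == "SG")
  cys_uid_all <- unique(residue_uid(at$chain, at$res_seq, at$icode)[
    at$res_name == "CYS"])
  sg_uid <- residue_uid(at$chain, at$res_seq, at$icode)[cys]
  missing_sg <- setdiff(cys_uid_all, sg_uid)
  if (length(missing_sg))
    warn_sctraj("cysteine(s) without SG atom skipped: %s",
                paste(missing_sg, collapse = ", "))

  empty <- data.frame(chain_u = character(0), res_seq_u = integer(0),
                      icode_u = character(0), chain_v = character(0),
                      res_seq_v = integer(0), icode_v = character(0),
                      sg_dist_A = numeric(0), stringsAsFactors = FALSE)
  if (length(cys) < 2) return(empty)

  xyz <- frame$xyz[cys, , drop = FALSE]
  D <- as.matrix(stats::dist(xyz))
  pr <- which(upper.tri(D) & D < sg_cutoff_A, arr.ind = TRUE)
  if (nrow(pr) == 0) return(empty)
  ord <- order(D[pr])
  pr <- pr[ord, , drop = FALSE]
  used <- logical(length(cys))
  keep <- logical(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  pr <- pr[keep, , drop = FALSE]
  ai <- cys[pr[, 1]]; aj <- cys[pr[, 2]]
  u <- at[ai, ]; v <- at[aj, ]
  swap <- canonical_pair_order(u$chain, u$res_seq, u$icode,
                               v$chain, v$res_seq, v$icode)
  tmp_ai <- ifelse(swap, aj, ai); aj <- ifelse(swap, ai, aj); ai <- tmp_ai
  u <- at[ai, ]; v <- at[aj, ]
  out <- data.frame(
    chain_u = u$chain, res_seq_u = u$res_seq, icode_u = u$icode,
    chain_v = v$chain, res_seq_v = v$res_seq, icode_v = v$icode,
    sg_dist_A = D[pr],
    stringsAsFactors = FALSE
  )
  out[order(out$chain_u, out$res_seq_u, out$chain_v, out$res_seq_v), ,
      drop = FALSE]
}
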