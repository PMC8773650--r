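# Stabilization-center dynamics across a trajectory: occupancy time series,
# extracellular / occurrence filters, and topological classification.

#' Assembly topology configuration
#'
#' Maps each chain to a hemichannel and records the extracellular residue
#' intervals and the occupancy filter threshold.  Defaults mirror a connexin
#' gap-junction channel: extracellular loops EL1 = residues 47-73 and
#' EL2 = 177-203, and an occurrence filter keeping stabilization centers
#' present in at least 2% of frames.
#'
#' @param hemichannel_of Named character vector mapping chain IDs to
#'   `"HC1"` or `"HC2"`.
#' @param extracellular_ranges List of inclusive `c(lo, hi)` residue-number
#'   intervals (default `list(c(47, 73), c(177, 203))`).
#' @param min_occurrence_frac Minimum occupancy retained by
#'   [filter_occurrence()] (default 0.02, inclusive).
#' @return An object of class `topology_config`.
#' @export
topology_config <- function(hemichannel_of,
                            extracellular_ranges = list(c(47, 73),
                                                        c(177, 203)),
                            min_occurrence_frac = 0.02) {
  if (is.null(names(hemichannel_of)) || any(names(hemichannel_of) == ""))
    stop_sctraj("sctraj_config", "hemichannel_of must be a named vector")
  if (!all(hemichannel_of %in% c("HC1", "HC2")))
    stop_sctraj("sctraj_config", "hemichannel labels must be HC1 or HC2")
  for (r in extracellular_ranges)
    if (length(r) != 2 || r[1] > r[2])
      stop_sctraj("sctraj_config", "extracellular range must be c(lo, hi)")
  if (length(extracellular_ranges) >= 2) {
    m <- do.call(rbind, extracellular_ranges)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      stop_sctraj("sctraj_config", "extracellular ranges must not overlap")
  }
  if (min_occurrence_frac < 0 || min_occurrence_frac > 1)
    stop_sctraj("sctraj_config", "min_occurrence_frac must be in [0, 1]")
  structure(list(hemichannel_of = hemichannel_of,
                 extracellular_ranges = extracellular_ranges,
                 min_occurrence_frac = min_occurrence_frac),
            class = "topology_config")
}

# Which extracellular interval (index) each residue number falls in; 0 = none.
extracellular_interval <- function(res_seq, topo) {
  out <- integer(length(res_seq))
  for (k in seq_along(topo$extracellular_ranges)) {
    r <- topo$extracellular_ranges[[k]]
    out[res_seq >= r[1] & res_seq <= r[2]] <- k
  }
  out
}

#' Track stabilization centers across a trajectory
#'
#' Runs [find_stabilization_centers()] on every frame and collects, for every
#' residue pair that is a stabilization center in at least one frame, its
#' per-frame presence and occupancy (fraction of frames present; the
#' denominator counts all frames).
#'
#' @param traj A trajectory.
#' @inheritParams find_stabilization_centers
#' @return An object of class `sc_series`: a list with `pairs` (one row per
#'   pair: identities, class placeholder, mean minimum distance over present
#'   frames, first/last frame present), `presence` (frames x pairs logical
#'   matrix) and `occupancy` accessor via `$pairs$occupancy`.
#' @export
sc_time_series <- function(traj, vdw = default_vdw_table(),
                           cparams = contact_params(),
                           sparams = sc_params()) {
  nf <- n_frames(traj)
  if (nf < 1) stop_sctraj("sctraj_empty", "trajectory has no frames")
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    sc <- find_stabilization_centers(get_frame(traj, f), vdw, cparams,
                                     sparams)
    sc$frame <- rep(f, nrow(sc))
    per_frame[[f]] <- sc
  }
  all_sc <- do.call(rbind, per_frame)
  if (is.null(all_sc) || nrow(all_sc) == 0) {
    return(structure(list(
      pairs = data.frame(), presence = matrix(FALSE, nf, 0),
      frame_interval_ps = traj$frame_interval_ps), class = "sc_series"))
  }
  key <- pair_key(all_sc$uid_u, all_sc$uid_v)
  ukey <- sort(unique(key))
  presence <- matrix(FALSE, nf, length(ukey),
                     dimnames = list(NULL, ukey))
  presence[cbind(all_sc$frame, match(key, ukey))] <- TRUE

  first <- !duplicated(key)
  pairs <- all_sc[first, c("chain_u", "res_seq_u", "icode_u", "res_name_u",
                           "chain_v", "res_seq_v", "icode_v", "res_name_v",
                           "uid_u", "uid_v")]
  pairs <- pairs[match(ukey, key[first]), , drop = FALSE]
  pairs$mean_min_dist_A <- as.vector(
    tapply(all_sc$min_dist_A, factor(key, levels = ukey), mean))
  pairs$occupancy <- colMeans(presence)
  pairs$first_frame <- apply(presence, 2, function(p) which(p)[1])
  pairs$last_frame <- apply(presence, 2, function(p) max(which(p)))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, presence = presence,
                 frame_interval_ps = traj$frame_interval_ps),
            class = "sc_series")
}

#' @export
print.sc_series <- function(x, ...) {
  cat(sprintf("<sc_series> %d pairs over %d frames\n",
              ncol(x$presence), nrow(x$presence)))
  invisible(x)
}

subset_series <- function(series, keep) {
  series$pairs <- series$pairs[keep, , drop = FALSE]
  rownames(series$pairs) <- NULL
  series$presence <- series$presence[, keep, drop = FALSE]
  series
}

#' Keep stabilization centers with at least one extracellular residue
#'
#' A pair is retained when at least one member residue's number falls in an
#' extracellular interval (boundaries inclusive).
#'
#' @param series An `sc_series` from [sc_time_series()].
#' @param topo A [topology_config()].
#' @return The filtered `sc_series`.
#' @export
filter_extracellular <- function(series, topo) {
  if (nrow(series$pairs) == 0) return(series)
  keep <- extracellular_interval(series$pairs$res_seq_u, topo) > 0 |
    extracellular_interval(series$pairs$res_seq_v, topo) > 0
  subset_series(series, keep)
}

#' Keep stabilization centers above the occupancy threshold
#'
#' Retains pairs whose occupancy is at least `min_occurrence_frac`
#' (inclusive: "at least 2%" keeps a pair present in exactly 2% of frames).
#'
#' @inheritParams filter_extracellular
#' @return The filtered `sc_series`.
#' @export
filter_occurrence <- function(series, topo) {
  if (nrow(series$pairs) == 0) return(series)
  keep <- series$pairs$occupancy >= topo$min_occurrence_frac
  subset_series(series, keep)
}

#' Classify a stabilization center by assembly topology
#'
#' * different hemichannels -> `TRANS_GJ` (the docking interface proper);
#' * same hemichannel, different chains -> `INTER_SUBUNIT_INTRA_HC`;
#' * same chain, residues in different extracellular intervals ->
#'   `INTRA_SUBUNIT_INTER_LOOP`;
#' * same chain, same extracellular interval -> `INTRA_LOOP`;
#' * same chain otherwise -> `OTHER`.
#'
#' @param chain_u,chain_v Chain IDs (vectors accepted).
#' @param res_seq_u,res_seq_v Residue numbers.
#' @param topo A [topology_config()]; every chain must be mapped.
#' @return Character vector of class labels.
#' @export
classify_sc <- function(chain_u, res_seq_u, chain_v, res_seq_v, topo) {
  hc <- topo$hemichannel_of
  bad <- setdiff(unique(c(chain_u, chain_v)), names(hc))
  if (length(bad))
    stop_sctraj("sctraj_config", "chain(s) not mapped to a hemichannel: %s",
                paste(bad, collapse = ", "))
  hu <- unname(hc[chain_u]); hv <- unname(hc[chain_v])
  iu <- extracellular_interval(res_seq_u, topo)
  iv <- extracellular_interval(res_seq_v, topo)
  out <- rep("OTHER", length(chain_u))
  same_chain <- chain_u == chain_v
  out[hu != hv] <- "TRANS_GJ"
  out[hu == hv & !same_chain] <- "INTER_SUBUNIT_INTRA_HC"
  out[same_chain & iu > 0 & iv > 0 & iu != iv] <- "INTRA_SUBUNIT_INTER_LOOP"
  out[same_chain & iu > 0 & iv > 0 & iu == iv] <- "INTRA_LOOP"
  out
}

#' Attach class labels to an `sc_series`
#' @inheritParams filter_extracellular
#' @return The series with a `class` column added to `$pairs`.
#' @export
classify_series <- function(series, topo) {
  if (nrow(series$pairs) == 0) return(series)
  series$pairs$class <- classify_sc(series$pairs$chain_u,
                                    series$pairs$res_seq_u,
                                    series$pairs$chain_v,
                                    series$pairs$res_seq_v, topo)
  series
}

#' Tidy summary of an `sc_series`
#' @param x An `sc_series`.
#' @param ... Unused.
#' @return The `$pairs` data frame.
#' @export
as.data.frame.sc_series <- function(x, ...) x$pairs
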