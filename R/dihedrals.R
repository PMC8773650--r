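# Backbone dihedral angles and the association between proline psi states
# and stabilization-center presence.

#' Dihedral angle of four points
#'
#' IUPAC sign convention (trans = 180, cis = 0; the same convention as VMD,
#' bio3d and MDAnalysis).  Vectorized: the four arguments may be matrices
#' with one row per observation.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors or n x 3 matrices (Angstrom).
#' @return Angle(s) in degrees, wrapped to (-180, 180].
#' @export
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))  # 180
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- rowSums(b1^2); n2 <- rowSums(b2^2); n3 <- rowSums(b3^2)
  if (any(n1 < 1e-12 | n2 < 1e-12 | n3 < 1e-12))
    stop_sctraj("sctraj_degenerate", "coincident consecutive points")
  cr12 <- cross3(b1, b2)
  cr23 <- cross3(b2, b3)
  if (any(rowSums(cr12^2) < 1e-16 * n1 * n2 |
          rowSums(cr23^2) < 1e-16 * n2 * n3))
    stop_sctraj("sctraj_degenerate", "collinear consecutive points")
  y <- sqrt(n2) * rowSums(b1 * cr23)
  x <- rowSums(cr12 * cr23)
  ang <- atan2(y, x) * 180 / pi
  unname(wrap_deg(ang))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# wrap to (-180, 180]
wrap_deg <- function(ang) {
  ang <- (ang + 180) %% 360 - 180
  ang[ang == -180] <- 180
  ang
}

# Coordinates of one named atom of one residue across all frames (n_frames x 3),
# or NULL if the atom is absent.
atom_coords_series <- function(traj, chain, res_seq, icode, atom_name) {
  at <- traj$atoms
  i <- which(at$chain == chain & at$res_seq == res_seq &
               at$icode == icode & at$atom_name == atom_name)
  if (length(i) == 0) return(NULL)
  t(traj$coords[i[1], , , drop = TRUE])
}

#' Backbone dihedral series for one residue across a trajectory
#'
#' Definitions: `phi(i) = C(i-1), N(i), CA(i), C(i)`;
#' `psi(i) = N(i), CA(i), C(i), N(i+1)`;
#' `omega(i) = CA(i-1), C(i-1), N(i), CA(i)`.
#' Sequence neighbours are the residues numbered `res_seq - 1` / `res_seq + 1`
#' on the same chain; a terminal residue lacking the needed neighbour (or a
#' residue missing a required backbone atom) raises a not-computable error.
#' Frames with degenerate geometry yield `NA`.
#'
#' @param traj A trajectory.
#' @param chain Chain ID.
#' @param res_seq Residue number.
#' @param kind One of `"phi"`, `"psi"`, `"omega"`.
#' @param icode Insertion code (default none).
#' @return An object of class `dihedral_series`: residue identity, kind and
#'   `values_deg` (one angle per frame, degrees in (-180, 180]).
#' @export
residue_dihedral_series <- function(traj, chain, res_seq,
                                    kind = c("phi", "psi", "omega"),
                                    icode = "") {
  kind <- match.arg(kind)
  spec <- switch(kind,
    phi   = list(c(-1, 0, 0, 0), c("C", "N", "CA", "C")),
    psi   = list(c(0, 0, 0, 1),  c("N", "CA", "C", "N")),
    omega = list(c(-1, -1, 0, 0), c("CA", "C", "N", "CA"))
  )
  pts <- vector("list", 4)
  for (k in 1:4) {
    rs <- res_seq + spec[[1]][k]
    ic <- if (spec[[1]][k] == 0) icode else ""
    p <- atom_coords_series(traj, chain, rs, ic, spec[[2]][k])
    if (is.null(p))
      stop_sctraj("sctraj_not_computable",
                  "%s(%s:%d%s) needs atom %s of residue %d, which is absent",
                  kind, chain, res_seq, icode, spec[[2]][k], rs)
    pts[[k]] <- p
  }
  nf <- n_frames(traj)
  vals <- tryCatch(
    dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
    sctraj_degenerate = function(e) {
      # fall back frame by frame so only degenerate frames become NA
      vapply(seq_len(nf), function(f) {
        tryCatch(dihedral_angle(pts[[1]][f, ], pts[[2]][f, ],
                                pts[[3]][f, ], pts[[4]][f, ]),
                 sctraj_degenerate = function(e) NA_real_)
      }, numeric(1))
    })
  structure(list(chain = chain, res_seq = res_seq, icode = icode,
                 kind = kind, values_deg = vals),
            class = "dihedral_series")
}

#' Classify a proline omega angle as cis or trans
#'
#' `|omega| <= 90` degrees is cis (inclusive at the boundary); otherwise
#' trans (a stable trans proline sits near 180 degrees).
#'
#' @param omega_deg Numeric vector of omega angles in degrees.
#' @return Character vector `"cis"` / `"trans"`.
#' @export
classify_proline_isomer <- function(omega_deg) {
  if (any(!is.finite(omega_deg)))
    stop_sctraj("sctraj_invalid", "omega angles must be finite")
  ifelse(abs(omega_deg) <= 90, "cis", "trans")
}

#' Psi-angle window
#'
#' Inclusive angular window for the in/out dihedral state, defaulting to the
#' 0 to -45 degree range associated with interface loss.  Windows do not wrap
#' across +/-180.
#'
#' @param lo_deg,hi_deg Window bounds in degrees, `lo_deg <= hi_deg`.
#' @return An object of class `psi_window`.
#' @export
psi_window <- function(lo_deg = -45, hi_deg = 0) {
  if (lo_deg > hi_deg)
    stop_sctraj("sctraj_invalid", "window requires lo_deg <= hi_deg")
  structure(list(lo_deg = lo_deg, hi_deg = hi_deg), class = "psi_window")
}

in_window <- function(values, window) {
  is.finite(values) & values >= window$lo_deg & values <= window$hi_deg
}

#' Association between stabilization-center presence and a psi window
#'
#' Each frame is "in window" when ANY (default) or ALL of the supplied psi
#' series fall inside the window (the any-rule captures "either of the
#' opposing subunits").  The statistic reports the conditional occupancies
#' of the stabilization center given the window state, a Haldane-Anscombe
#' (+0.5) corrected odds ratio, and a permutation p-value obtained by
#' circularly shifting the presence vector (which preserves its
#' autocorrelation); the test statistic is the absolute difference of
#' conditional occupancies and
#' `p = (1 + #\{shifted >= observed\}) / (n_perm + 1)`.
#'
#' If every frame falls on one side of the window, or the stabilization
#' center is present (or absent) in every frame, the association is
#' undefined and the result is flagged (`flagged = TRUE`, `perm_p = NA`).
#'
#' @param sc_presence Logical vector of per-frame stabilization-center
#'   presence.
#' @param psi_series A `dihedral_series`, numeric vector, or list of them
#'   (one per tracked subunit), all of the same length as `sc_presence`.
#' @param window A [psi_window()].
#' @param n_perm Number of circular-shift permutations (default 1000).
#' @param seed Integer seed making the permutation draw deterministic.
#' @param aggregate `"any"` (default) or `"all"` aggregation over psi series.
#' @return An object of class `sc_association`.
#' @export
correlate_sc_dihedral <- function(sc_presence, psi_series,
                                  window = psi_window(), n_perm = 1000,
                                  seed = 1, aggregate = c("any", "all")) {
  aggregate <- match.arg(aggregate)
  if (n_perm < 1) stop_sctraj("sctraj_invalid", "n_perm must be >= 1")
  s <- as.logical(sc_presence)
  n <- length(s)
  if (inherits(psi_series, "dihedral_series") || is.numeric(psi_series))
    psi_series <- list(psi_series)
  vals <- lapply(psi_series, function(p) {
    v <- if (inherits(p, "dihedral_series")) p$values_deg else p
    if (length(v) != n)
      stop_sctraj("sctraj_invalid", "psi series length != presence length")
    v
  })
  inw <- vapply(vals, in_window, logical(n), window = window)
  inw <- matrix(inw, nrow = n)
  w <- if (aggregate == "any") rowSums(inw) > 0 else rowSums(inw) == ncol(inw)

  a <- sum(w & s); b <- sum(w & !s); c <- sum(!w & s); d <- sum(!w & !s)
  occ_in <- if (a + b > 0) a / (a + b) else NA_real_
  occ_out <- if (c + d > 0) c / (c + d) else NA_real_
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))

  flagged <- (a + b == 0) || (c + d == 0) || all(s) || !any(s)
  if (flagged || n < 3) {
    return(structure(list(occ_in_window = occ_in, occ_out_window = occ_out,
                          odds_ratio = or, perm_p = NA_real_,
                          n_perm = as.integer(n_perm), seed = seed,
                          n_frames = n, flagged = TRUE,
                          table = c(a = a, b = b, c = c, d = d)),
                     class = "sc_association"))
  }

  obs <- abs(occ_in - occ_out)
  n_in <- a + b
  n_out <- c + d
  perm_stat <- with_seed(seed, {
    shifts <- sample.int(n - 1, n_perm, replace = TRUE)
    vapply(shifts, function(k) {
      sk <- s[((seq_len(n) - 1 + k) %% n) + 1]
      abs(sum(w & sk) / n_in - sum(!w & sk) / n_out)
    }, numeric(1))
  })
  p <- (1 + sum(perm_stat >= obs)) / (n_perm + 1)
  structure(list(occ_in_window = occ_in, occ_out_window = occ_out,
                 odds_ratio = or, perm_p = p, n_perm = as.integer(n_perm),
                 seed = seed, n_frames = n, flagged = FALSE,
                 table = c(a = a, b = b, c = c, d = d)),
            class = "sc_association")
}

#' @export
print.sc_association <- function(x, ...) {
  cat(sprintf(paste0("<sc_association> occ_in=%.3f occ_out=%.3f OR=%.3g ",
                     "perm_p=%s%s\n"),
              x$occ_in_window, x$occ_out_window, x$odds_ratio,
              format(x$perm_p), if (x$flagged) " [flagged: undefined]" else ""))
  invisible(x)
}
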