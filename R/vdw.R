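# Van der Waals radii.

#' Default van der Waals radius table
#'
#' Bondi (1964) radii for the elements found in protein heavy atoms and
#' hydrogens, plus a default radius used for unknown element symbols.  All
#' values are in Angstrom.  The contact criterion compares inter-atomic
#' distance against `radius(a) + radius(b) + margin`.
#'
#' @param default_radius Radius assigned to elements missing from the table
#'   (default 1.70, the carbon radius).
#' @return An object of class `vdw_table`.
#' @export
#' @examples
#' vdw <- default_vdw_table()
#' vdw_radius(vdw, c("C", "S", "Xx"))
default_vdw_table <- function(default_radius = 1.70) {
  radii <- c(
    H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
  )
  structure(list(radii = radii, default_radius = default_radius),
            class = "vdw_table")
}

#' Look up van der Waals radii by element symbol
#' @param vdw A `vdw_table`.
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom; unknown elements get the
#'   table's default radius.
#' @export
vdw_radius <- function(vdw, element) {
  r <- vdw$radii[toupper(element)]
  r[is.na(r)] <- vdw$default_radius
  unname(r)
}
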