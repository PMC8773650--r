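# Numbered residue lists for the connexin extracellular loops.

#' Parse a numbered residue list
#'
#' Parses strings of the form `"47D-48E-...-73S"` (dash-separated
#' `<number><one-letter code>` tokens) into a residue table.
#'
#' @param text A single string.
#' @return Data frame with `res_seq` (integer) and `aa` (one-letter code).
#' @export
#' @examples
#' parse_numbered_sequence("54C-55N-56T")
parse_numbered_sequence <- function(text) {
  tokens <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  ok <- grepl("^[0-9]+[A-Za-z]$", tokens)
  if (!all(ok))
    stop_sctraj("sctraj_invalid", "malformed residue token: %s",
                tokens[!ok][1])
  data.frame(
    res_seq = as.integer(sub("[A-Za-z]$", "", tokens)),
    aa = toupper(sub("^[0-9]+", "", tokens)),
    stringsAsFactors = FALSE
  )
}

#' Connexin-43 extracellular loop residue tables
#'
#' The EL1 (residues 47-73) and EL2 (177-203) sequences of human Cx43 in
#' author numbering, parsed from the numbered lists shipped with the package.
#' EL1 carries the three conserved cysteines 54C, 61C, 65C and EL2 carries
#' 187C, 192C, 198C.
#'
#' @return Named list of two data frames (`EL1`, `EL2`) with `res_seq`, `aa`
#'   and `loop` columns.
#' @export
cx43_el_sequences <- function() {
  path <- system.file("extdata", "cx43_el_sequences.txt", package = "sctraj")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    df <- parse_numbered_sequence(parts[2])
    df$loop <- parts[1]
    out[[parts[1]]] <- df
  }
  out
}
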