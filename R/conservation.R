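# Per-column consensus agreement on a supplied multiple alignment, with the
# Jalview-style percent-identity colour categories.

#' Read an aligned FASTA file
#'
#' All records must have the same gapped length; `-` and `.` are treated as
#' gaps and residues are uppercased on read.  Computing the alignment itself
#' is out of scope: this consumes one.
#'
#' @param path Path to an aligned FASTA file with at least 2 records.
#' @param reference_id ID of the reference sequence (default: the first
#'   record).
#' @return An object of class `msa_alignment`: a character matrix (one row
#'   per sequence, one column per alignment column) plus the reference ID.
#' @export
read_fasta_alignment <- function(path, reference_id = NULL) {
  if (!file.exists(path))
    stop_sctraj("sctraj_io", "cannot read alignment: %s", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) < 2)
    stop_sctraj("sctraj_alignment", "alignment needs >= 2 sequences")
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  new_alignment(seqs, reference_id)
}

#' Construct an alignment object from gapped strings
#' @param seqs Named character vector of equal-length gapped sequences.
#' @param reference_id Reference sequence ID (default first).
#' @return An `msa_alignment`.
#' @export
new_alignment <- function(seqs, reference_id = NULL) {
  if (length(unique(nchar(seqs))) != 1)
    stop_sctraj("sctraj_alignment",
                "ragged alignment: sequence lengths differ (%s)",
                paste(unique(nchar(seqs)), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  reference_id <- reference_id %||% names(seqs)[1]
  if (!reference_id %in% names(seqs))
    stop_sctraj("sctraj_alignment", "reference %s not in alignment",
                reference_id)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  structure(list(mat = mat, ids = names(seqs), reference_id = reference_id),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns (reference: %s)\n",
              nrow(x$mat), ncol(x$mat), x$reference_id))
  invisible(x)
}

#' Per-column consensus agreement and identity category
#'
#' For each column the consensus is the most frequent non-gap residue (ties
#' broken alphabetically) and the agreement is
#' `100 * count(consensus) / count(non-gap)` (or `/ n_sequences` when
#' `include_gaps = TRUE`).  Categories follow the percent-identity colour
#' thresholds: agreement > 80 -> `DARK_BLUE`, > 60 -> `PALE_BLUE`,
#' > 40 -> `MAGENTA`, otherwise `RED` (strict inequalities: exactly 40 is
#' `RED`).  All-gap columns get agreement 0, `RED`, and are flagged.
#'
#' @param aln An `msa_alignment`.
#' @param include_gaps Count gaps in the denominator (default FALSE).
#' @return Data frame with `column_index`, `consensus_residue`,
#'   `agreement_pct`, `category`, `all_gap`.
#' @export
column_stats <- function(aln, include_gaps = FALSE) {
  m <- aln$mat
  nseq <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nongap <- col[col != "-"]
    if (length(nongap) == 0) {
      return(data.frame(column_index = j, consensus_residue = "-",
                        agreement_pct = 0, category = "RED",
                        all_gap = TRUE, stringsAsFactors = FALSE))
    }
    counts <- table(nongap)
    best <- max(counts)
    consensus <- sort(names(counts)[counts == best])[1]
    denom <- if (include_gaps) nseq else length(nongap)
    pct <- 100 * best / denom
    data.frame(column_index = j, consensus_residue = consensus,
               agreement_pct = pct, category = identity_category(pct),
               all_gap = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percent-identity category for an agreement percentage
#' @param agreement_pct Numeric vector in `[0, 100]`.
#' @return `DARK_BLUE` (> 80), `PALE_BLUE` (> 60), `MAGENTA` (> 40) or
#'   `RED` (<= 40).
#' @export
identity_category <- function(agreement_pct) {
  ifelse(agreement_pct > 80, "DARK_BLUE",
         ifelse(agreement_pct > 60, "PALE_BLUE",
                ifelse(agreement_pct > 40, "MAGENTA", "RED")))
}

#' Extract the alignment columns spanning a reference residue range
#'
#' Selects the columns between the reference's `lo`-th and `hi`-th residue
#' (in reference numbering; see `ref_start`), keeping columns where the
#' reference has an internal gap.
#'
#' @param aln An `msa_alignment`.
#' @param ref_range Inclusive `c(lo, hi)` interval in reference residue
#'   numbering.
#' @param ref_start Residue number of the first (ungapped) reference residue
#'   (default 1; set e.g. 47 when the alignment starts at residue 47).
#' @return The sub-alignment as an `msa_alignment`.
#' @export
extract_reference_range <- function(aln, ref_range, ref_start = 1) {
  if (length(ref_range) != 2 || ref_range[1] > ref_range[2])
    stop_sctraj("sctraj_range", "ref_range must be c(lo, hi) with lo <= hi")
  ref <- aln$mat[aln$reference_id, ]
  res_cols <- which(ref != "-")
  numbers <- seq(from = ref_start, length.out = length(res_cols))
  lo_i <- match(ref_range[1], numbers)
  hi_i <- match(ref_range[2], numbers)
  if (is.na(lo_i) || is.na(hi_i))
    stop_sctraj("sctraj_range",
                "range %d-%d outside reference residues %d-%d",
                ref_range[1], ref_range[2], numbers[1],
                numbers[length(numbers)])
  cols <- seq(res_cols[lo_i], res_cols[hi_i])
  sub <- apply(aln$mat[, cols, drop = FALSE], 1, paste, collapse = "")
  new_alignment(sub, aln$reference_id)
}
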