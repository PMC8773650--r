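# Internal helpers shared across modules.

# Classed errors so callers/tests can distinguish failure modes.
stop_sctraj <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sctraj_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_sctraj <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical residue identifier: "<chain>:<res_seq><icode>".
residue_uid <- function(chain, res_seq, icode = "") {
  paste0(chain, ":", res_seq, ifelse(icode == "" | is.na(icode), "", icode))
}

# Canonical unordered pair key; order residues by (chain, res_seq, icode).
canonical_pair_order <- function(chain_u, res_seq_u, icode_u,
                                 chain_v, res_seq_v, icode_v) {
  swap <- (chain_v < chain_u) |
    (chain_v == chain_u & res_seq_v < res_seq_u) |
    (chain_v == chain_u & res_seq_v == res_seq_u & icode_v < icode_u)
  swap
}

pair_key <- function(uid_u, uid_v) {
  paste(pmin(uid_u, uid_v), pmax(uid_u, uid_v), sep = "--")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
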