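#!/usr/bin/env Rscript
# Proline dihedral analysis: psi series for residues 59, 191, 193 of the
# interface subunits, cis/trans classification of omega where computable,
# and the psi(193) / trans-interface association statistic, including a
# fidelity sweep showing the odds ratio rising with the planted coupling.
# Writes tables under results/dihedrals/.

suppressPackageStartupMessages(library(sctraj))
seed <- 1
out_dir <- "results/dihedrals"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

traj <- read_pdb("results/synthetic/trajectory_close.pdb")
pres <- read.delim("results/synthetic/truth_presence_close.tsv")
trans_key <- grep("^D", names(pres), value = TRUE)[1]
sc_presence <- pres[[trans_key]] == 1

# psi series of the tracked prolines in the two interface subunits
rows <- list()
for (ch in c("D", "G")) for (rs in c(59, 191, 193)) {
  ds <- tryCatch(residue_dihedral_series(traj, ch, rs, "psi"),
                 error = function(e) NULL)
  if (!is.null(ds))
    rows[[length(rows) + 1]] <- data.frame(
      chain = ch, res_seq = rs, frame = seq_along(ds$values_deg),
      psi_deg = ds$values_deg)
}
psi_tab <- do.call(rbind, rows)
write.table(psi_tab, file.path(out_dir, "psi_series.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

psiD <- residue_dihedral_series(traj, "D", 193, "psi")
psiG <- residue_dihedral_series(traj, "G", 193, "psi")
assoc <- correlate_sc_dihedral(sc_presence, list(psiD, psiG),
                               psi_window(-45, 0), n_perm = 999,
                               seed = seed)
message(sprintf(
  "psi(193) association: occ_in=%.3f occ_out=%.3f OR=%.3g perm_p=%.4g",
  assoc$occ_in_window, assoc$occ_out_window, assoc$odds_ratio,
  assoc$perm_p))
write.table(data.frame(
  pair = trans_key, occ_in_window = assoc$occ_in_window,
  occ_out_window = assoc$occ_out_window, odds_ratio = assoc$odds_ratio,
  perm_p = assoc$perm_p, n_perm = assoc$n_perm, seed = seed),
  file.path(out_dir, "association.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

# fidelity sweep on the statistical generator
sweep <- do.call(rbind, lapply(c(0.5, 0.7, 0.9, 1.0), function(f) {
  sim <- simulate_coupled_series(1500, occupancy = 0.5, fidelity = f,
                                 sense = "pro", seed = seed + 100)
  a <- correlate_sc_dihedral(sim$presence, sim$psi, n_perm = 499,
                             seed = seed + 200)
  data.frame(fidelity = f, odds_ratio = a$odds_ratio, perm_p = a$perm_p)
}))
write.table(sweep, file.path(out_dir, "fidelity_sweep.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("fidelity sweep odds ratios: ",
        paste(sprintf("%.3g", sweep$odds_ratio), collapse = " -> "))
message("done")
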