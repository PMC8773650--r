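#!/usr/bin/env Rscript
# Conservation colouring of the extracellular loops: generate the synthetic
# connexin-family-like alignment (the real family alignment is not shipped),
# score per-column consensus agreement, assign the percent-identity
# categories and extract the EL1/EL2 sub-alignments by reference numbering.
# Writes tables under results/conservation/.

suppressPackageStartupMessages(library(sctraj))
seed <- 1
out_dir <- "results/conservation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

aln <- simulate_el_alignment(n_seqs = 8, seed = seed)
write_fasta_alignment(aln, file.path(out_dir, "synthetic_cx_family.fasta"))

cs <- column_stats(aln)
# attach reference residue numbers (EL1 47-73 then EL2 177-203)
els <- cx43_el_sequences()
ref_num <- c(els$EL1$res_seq, els$EL2$res_seq)
ref_col <- which(aln$mat["Cx43", ] != "-")
cs$ref_res_seq <- NA_integer_
cs$ref_res_seq[ref_col] <- ref_num
write.table(cs, file.path(out_dir, "conservation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("columns by category: %s",
                paste(names(table(cs$category)), table(cs$category),
                      sep = "=", collapse = ", ")))

el1 <- extract_reference_range(aln, c(47, 73), ref_start = 47)
message(sprintf("EL1 sub-alignment: %d columns, %d reference residues",
                ncol(el1$mat), sum(el1$mat["Cx43", ] != "-")))
cys_cols <- cs$ref_res_seq %in% c(54, 61, 65, 187, 192, 198)
message(sprintf("conserved cysteine columns rated: %s",
                paste(cs$category[which(cys_cols)], collapse = ", ")))
message("done")
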