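# sctraj

Stabilization-center dynamics in multi-chain protein assemblies, built for
gap-junction channel (GJC) models.

Gap-junction channels are dodecamers: two hexameric connexin hemichannels
(HC1, HC2), one per membrane, dock through their extracellular loops EL1
(Cx43 residues 47–73) and EL2 (177–203).  Each loop carries three conserved
cysteines (54, 61, 65 / 187, 192, 198) forming the intra-subunit disulfides
54–198, 61–192 and 65–187.  `sctraj` analyses how such an interface holds
together through **protein stabilization centers (SCs)**: residue pairs
(u, v), far apart in sequence or on different chains, with

* at least one heavy-atom pair closer than
  `r_vdW(a) + r_vdW(b) + 1 Å` (strict), and
* a densely interacting neighbourhood: ≥ 7 of the 9 contact candidates on
  the 3×3 grid of sequence-neighbour triplets `{u−1,u,u+1} × {v−1,v,v+1}`
  are themselves in contact.

For a multi-model PDB trajectory the package computes per-frame SC sets,
per-pair occupancies (fraction of frames present), applies the
extracellular (≥ 1 residue in 47–73 ∪ 177–203) and occurrence (≥ 2% of
frames) filters, classifies every retained pair by topology (`TRANS_GJ`,
`INTER_SUBUNIT_INTRA_HC`, `INTRA_SUBUNIT_INTER_LOOP`, `INTRA_LOOP`,
`OTHER`), detects disulfides (SG–SG < 2.5 Å, greedy matching), extracts
φ/ψ/ω backbone dihedral series, and tests the association between a
proline ψ window (default 0° to −45°) and SC presence with conditional
occupancies, a Haldane–Anscombe corrected odds ratio and a
circular-shift permutation p-value.  A conservation module scores
per-column consensus agreement of a supplied loop alignment with the
percent-identity categories (> 80% dark blue, > 60% pale blue, > 40%
magenta, else red).

Because raw MD trajectories of this system are not generally available,
the package includes a synthetic generator (`build_toy_assembly()`,
`plant_and_roll()`) that emulates the 6+6-chain double-hexamer with exact
frame-level ground truth — planted SC pairs with chosen support counts and
occupancies, planted disulfides in "close"/"open" modes, and a ψ angle
coupled to interface-SC presence with chosen fidelity — so the entire
pipeline is validated end to end.

## Worked example

```r
library(sctraj)

asm    <- build_toy_assembly(assembly_spec(chains_per_ring = 6, seed = 1))
rolled <- plant_and_roll(asm, default_plant_spec(asm, n_frames = 100, seed = 1))

ser <- sc_time_series(rolled$trajectory)
ser <- filter_occurrence(filter_extracellular(ser, asm$topology), asm$topology)
ser <- classify_series(ser, asm$topology)
ser$pairs[, c("chain_u", "res_seq_u", "chain_v", "res_seq_v", "class", "occupancy")]
#>   chain_u res_seq_u chain_v res_seq_v                    class occupancy
#> 1       A        52       A        65               INTRA_LOOP       0.3
#> 2       D        54       D       198 INTRA_SUBUNIT_INTER_LOOP       0.6
#> 3       D        55       G        56                 TRANS_GJ       0.9

nrow(detect_disulfides(get_frame(rolled$trajectory, 1)))
#> [1] 36     # 3 bonds x 12 chains, all at ~2.05 A

psiD <- residue_dihedral_series(rolled$trajectory, "D", 193, "psi")
psiG <- residue_dihedral_series(rolled$trajectory, "G", 193, "psi")
correlate_sc_dihedral(rolled$truth$presence[, 1], list(psiD, psiG),
                      psi_window(-45, 0), n_perm = 999, seed = 1)
#> <sc_association> occ_in=0.500 occ_out=0.976 OR=0.0303 perm_p=0.001
```

The three planted stabilization centers — the trans-interface pair at the
EL1 docking residues 55–56 between facing subunits D and G, the EL1–EL2
pair at the central cysteines 54–198, and the intra-EL1 pair 52–65 — are
recovered with their exact planted occupancies and classes.  The ψ(193)
association shows the planted anti-coupling: the trans-interface SC is
present in 97.6% of frames whose ψ stays outside the 0° to −45° window but
only 50% of in-window frames (fidelity 0.9), with a minimal permutation
p-value.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (build + roll, close and open disulfide modes),
`02_sc_dynamics.R` (detection, filters, classification, recovery check),
`03_dihedrals.R` (ψ series, association, fidelity sweep),
`04_conservation.R` (synthetic family alignment, identity categories).
Each writes its tables under `results/`.

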