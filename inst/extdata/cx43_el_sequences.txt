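# Human connexin-43 (Cx43) extracellular loop sequences in author residue
# numbering, written as dash-separated <number><one-letter residue> tokens.
EL1	47D-48E-49Q-50S-51A-52F-53R-54C-55N-56T-57Q-58Q-59P-60G-61C-62E-63N-64V-65C-66Y-67D-68K-69S-70F-71P-72I-73S
EL2	177Y-178G-179F-180S-181L-182S-183A-184V-185Y-186T-187C-188K-189R-190D-191P-192C-193P-194H-195Q-196V-197D-198C-199F-200L-201S-202R-203P
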