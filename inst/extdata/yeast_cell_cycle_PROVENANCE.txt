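yeast_cell_cycle.tsv
--------------------
Directed signed interaction graph of the budding-yeast cell-cycle boolean
network of Li F, Long T, Lu Y, Ouyang Q, Tang C, "The yeast cell-cycle
network is robustly designed", PNAS 101(14):4781-4786 (2004), Figure 1.
Transcribed by hand from the published figure: 11 nodes, 15 activating
(green) and 14 inhibiting (red) directed edges between distinct nodes,
plus the 5 inhibitory self-degradation loops (yellow) on Cln3, Cln1_2,
Swi5, Cdc20_Cdc14 and Mcm1_SFF. Node labels use underscores in place of
commas/slashes (Cln1_2 = "Cln1,2", Cdc20_Cdc14 = "Cdc20 and Cdc14",
Mcm1_SFF = "Mcm1/SFF").

Transcription checks (run by the package's test suite): symmetrizing with
self-loops dropped yields 23 undirected edges, 10 of them negative, with
exactly one incompatible directed pair (Clb1_2 -> Cdc20_Cdc14 activating
vs Cdc20_Cdc14 -| Clb1_2 inhibiting) removed; the exact frustration index
of the symmetrized network is 4.
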