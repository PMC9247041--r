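quantity	value
n_lncRNAs	1500
n_loci	887
n_homologous	65
n_arabidopsis_homologs	21
n_cis_targets	7103
n_trans_targets	4186
n_dels	575
n_positionally_conserved	651
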