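# Default universal single-copy marker set (43 ids), editable configuration.
# Synthetic stand-in list of broadly conserved single-copy genes (ribosomal
# proteins and core information-processing genes); replace with the marker
# collection appropriate for the lineage under study.
Ribosomal_L1
Ribosomal_L2
Ribosomal_L3
Ribosomal_L4
Ribosomal_L5
Ribosomal_L6
Ribosomal_L10
Ribosomal_L11
Ribosomal_L13
Ribosomal_L14
Ribosomal_L15
Ribosomal_L16
Ribosomal_L18
Ribosomal_L22
Ribosomal_L23
Ribosomal_L24
Ribosomal_L29
Ribosomal_L30
Ribosomal_S2
Ribosomal_S3
Ribosomal_S4
Ribosomal_S5
Ribosomal_S7
Ribosomal_S8
Ribosomal_S9
Ribosomal_S10
Ribosomal_S11
Ribosomal_S12
Ribosomal_S13
Ribosomal_S15
Ribosomal_S16
Ribosomal_S17
Ribosomal_S19
RNA_pol_alpha_rpoA
RNA_pol_beta_rpoB
RNA_pol_beta_prime_rpoC
Translation_IF2_infB
Preprotein_translocase_secY
Signal_recognition_ffh
Elongation_factor_Ts_tsf
Phosphoglycerate_kinase_pgk
Recombinase_recA
DNA_gyrase_A_gyrA
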