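compound,solvent,dose,sw_mean,sw_sd,sw_pred_a,sw_pred_b,sc_mean,sc_sd,sc_pred_a,sc_pred_b,dd_mean,dd_sd,dd_pred_a,dd_pred_b
6-Methylcoumarin,pbs,4.21,0.14,0.08,0.01,3.62,0.01,,0.04,0.01,4.06,0.14,3.59,0.47
Vanillin,pbs,3.3,0.72,0.24,0,1.80,0.06,0.02,0.44,0.20,1.92,0.33,2.85,1.28
7-Ethoxycoumarin,pbs,1.13,0.07,0.04,0,0.59,0,,0.04,0.02,1.08,0.06,1.06,0.48
4-Amino-3-nitrophenol,pbs,11.76,6.08,1.4,0.69,11.35,0.41,0.27,7.97,0.23,4.94,1.60,3.09,0.17
Caffeine,pbs,1.08,0.58,0.21,0,0,0.02,0.01,1.05,1.05,0.44,0.21,0.03,0.03
Benzoic Acid,pbs,7.92,4.33,0.61,0,4.20,0.17,0.08,0,0,2.74,0.64,7.92,3.60
Thioglycolic acid,pbs,72.46,47.69,5.12,0,41.19,4.32,1.23,0.93,0.25,10.28,6.69,71.53,19.21
2-5-Diaminotoluene sulfate,pbs,0.94,0.72,0.04,0,0,0.02,0.01,0.33,0.32,0.14,0.03,0.61,0.61
Propylparaben (experiment 2),pbs,2.51,0.75,0.15,0,0.60,0.03,0.02,0,0,1.66,0.23,2.51,1.52
Cyclophosphamide monohydrate,pbs,47.42,39.45,6.39,23.56,45.64,1.60,1.08,23.8,1.73,4.87,5.27,0.07,0.01
Resorcinol,pbs,97.86,16.69,5.79,0,69.81,5.13,2.96,0.01,0,72.61,8.89,97.85,27.98
Benzylidene acetone,pbs,3.91,0.25,0.04,0,0.01,0.06,0.01,0.01,0,2.83,0.15,3.90,1.70
Ibuprofen,pbs,2.51,1.89,0.42,0,0,0.11,0.06,0,0,0.56,0.41,2.51,2.50
Methylparaben,pbs,3.21,0.54,0.29,0,0.99,0.01,,0.02,0.01,2.47,0.30,3.19,1.34
2-Aminophenol,pbs,5.85,2.18,0.93,0,3.51,0.19,0.09,0.33,0.13,2.89,0.85,5.52,2.14
Anisyl alcohol,pbs,11.95,0.58,0.29,0.02,10.76,0.01,0.01,1.14,0.07,10.17,0.69,10.79,0.79
Cinnamic acid,pbs,1.62,1.16,0.14,0,0.64,0.05,0.02,0,0,0.39,0.14,1.62,0.70
2-Nitro-1-4-phenylenediamine,pbs,5.78,3.67,1.25,0.01,5.56,0.08,0.06,3.67,0.11,1.95,1.12,2.11,0.11
Cinnamyl Alcohol,pbs,6.72,0.28,0.19,0,0.01,0,,0,0,5.86,0.37,6.72,3.00
Diethanolamine,pbs,10.2,9.88,0.28,0,0,0.13,0.06,7.89,7.92,0.19,0.20,2.31,2.28
1-4-Phenylenediamine,pbs,0.91,0.49,0.06,0,0,0.09,0.03,0.43,0.42,0.17,0.06,0.48,0.48
Hydroquinone,pbs,15.73,9.05,1.90,0,9.33,1.54,0.87,1.08,0.44,4.01,2.59,14.65,5.95
2-Amino-3-methylimidazo[4-5-f]quinoline,pbs,3.21,2.37,0.33,0.01,2.98,0.51,0.26,1.23,0.08,0.29,0.21,1.97,0.15
4-Nitro-1-2-Phenylenediamine,pbs,1.18,0.54,0.11,0,1.12,0.05,0.01,0.39,0.02,0.55,0.09,0.79,0.05
Basic Red 76 (Chloride salt),pbs,53.27,51.10,0.78,45.69,52.15,0.48,0.21,7.58,1.12,0.12,0.11,0,0
HC Red No3,pbs,22.04,19.91,0.85,6.59,21.30,0.81,0.49,14.06,0.63,0.62,0.41,1.39,0.11
4-Bromophenyl isocyanate,ethanol,1.24,0.90,0.14,0,0,0.21,0.10,0,0,0.03,0.02,0.05,0.04
2-Acetylaminofluorene,ethanol,1.3,1.12,0.07,0.77,1.29,0.03,0.02,0.12,0,0.08,0.05,0.40,0.01
Testosterone,ethanol,1.64,1.41,0.13,0.01,1.35,0.07,0.03,0.27,0.05,0.08,0.06,1.36,0.24
Tetramethyl thiuram disulfide,ethanol,1.21,0.92,0.07,0,1.12,0.04,0.02,0.67,0.05,0.05,0.03,0.44,0.04
Triclosan,ethanol,1.81,1.41,0.07,0,1.30,0.22,0.07,0.12,0.03,0.08,0.02,1.69,0.48
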