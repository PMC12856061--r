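quantity,published,comparison,digits
volume_mean_BMP,7621,round,0
volume_mean_DIPY,6466,round,0
volume_mean_NS,6348,round,0
volume_sd_BMP,145,asis,0
volume_sd_DIPY,693,asis,0
volume_sd_NS,663,asis,0
volume_anova_p,0.036,round,3
microct_bridging_mean_BMP,90,round,0
microct_bridging_mean_DIPY,9,round,0
microct_bridging_mean_NS,10,round,0
microct_bridging_anova_p,0.001,less_than,NA
t_volume_BMP_vs_NS_p,0.02,round,2
t_volume_BMP_vs_DIPY_p,0.03,round,2
histology_interior_mean_BMP,65,round,0
histology_interior_mean_DIPY,39,round,0
histology_interior_mean_NS,27,round,0
histology_superficial_mean_BMP,48,round,0
histology_superficial_mean_DIPY,11,round,0
histology_superficial_mean_NS,3,round,0
histology_deep_mean_BMP,66,round,0
histology_deep_mean_DIPY,28,round,0
histology_deep_mean_NS,25,round,0
histology_interior_anova_p,0.226,round,3
histology_superficial_anova_p,0.114,round,3
histology_deep_anova_p,0.120,round,3
bridging_2mo_anova_p,0.073,round,3
bridging_4mo_anova_p,0.158,round,3
bridging_6mo_anova_p,0.450,round,3
bridging_8mo_anova_p,0.414,round,3
bridging_10mo_anova_p,0.404,round,3
bridging_12mo_anova_p,0.462,round,3
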