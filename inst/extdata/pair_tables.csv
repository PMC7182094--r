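disease,zygosity,n_concordant_unaffected,n_discordant,n_concordant_affected
hashimoto,MZ,17523,391,81
hashimoto,DZ,36339,1016,57
atrophic_gastritis,MZ,17803,183,9
atrophic_gastritis,DZ,36968,437,7
celiac,MZ,17855,93,47
celiac,DZ,36981,401,30
graves,MZ,17831,145,19
graves,DZ,37040,369,3
type1_diabetes,MZ,17900,74,21
type1_diabetes,DZ,37170,236,6
vitiligo,MZ,17933,56,6
vitiligo,DZ,37308,104,0
addison,MZ,17986,4,5
addison,DZ,37398,14,0
any_disease,MZ,16957,831,207
any_disease,DZ,34926,2335,151
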