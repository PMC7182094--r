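disease,stratum,n_cases,n_denominator
hashimoto,all,1683,110814
hashimoto,female,1410,58643
hashimoto,male,273,52171
atrophic_gastritis,all,652,110814
atrophic_gastritis,female,398,58643
atrophic_gastritis,male,254,52171
celiac,all,648,110814
celiac,female,433,58643
celiac,male,215,52171
graves,all,558,110814
graves,female,463,58643
graves,male,95,52171
type1_diabetes,all,364,110814
type1_diabetes,female,179,58643
type1_diabetes,male,185,52171
vitiligo,all,172,110814
vitiligo,female,95,58643
vitiligo,male,77,52171
addison,all,28,110814
addison,female,15,58643
addison,male,13,52171
any_disease,all,3882,110814
any_disease,female,2827,58643
any_disease,male,1055,52171
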