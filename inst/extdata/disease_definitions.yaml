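# Illustrative ascertainment rules for seven organ-specific autoimmune
# diseases. Code lists are editable defaults, not an authoritative registry
# protocol: review before use on real data.
hashimoto:
  inclusion:
    ICD10: ["E063"]
    ICD9: ["2452"]
    ICD8: ["245"]
    ICD7: ["253"]
  exclusion:
    ICD10: ["E060", "E061"]   # acute / subacute thyroiditis
    ICD9: ["2450", "2451"]
  required_atc:
    atc_prefix: "H03AA"        # levothyroxine
    min_dispensations: 2
    applies_if_alive_after: "2005-12-31"
atrophic_gastritis:
  inclusion:
    ICD10: ["K294", "D510"]    # atrophic gastritis; pernicious anemia
    ICD9: ["5351", "2810"]
    ICD8: ["2810"]
  exclusion:
    ICD10: ["K295"]            # unspecified chronic gastritis
  required_atc:
    atc_prefix: "B03BA"        # vitamin B12
    min_dispensations: 2
    applies_if_alive_after: "2005-12-31"
celiac:
  inclusion:
    ICD10: ["K900"]
    ICD9: ["5790"]
    ICD8: ["2690"]
  exclusion:
    ICD10: ["K901"]            # tropical sprue
graves:
  inclusion:
    ICD10: ["E050"]
    ICD9: ["2420"]
    ICD8: ["242"]
  exclusion:
    ICD10: ["E051", "E052"]    # toxic (multi)nodular goitre
type1_diabetes:
  inclusion:
    ICD10: ["E10"]
    ICD9: ["2500"]
  exclusion:
    ICD10: ["E11"]             # type 2 diabetes
  use_diabetes_register: true
vitiligo:
  inclusion:
    ICD10: ["L80"]
    ICD9: ["70901"]
addison:
  inclusion:
    ICD10: ["E271", "E272"]
    ICD9: ["2554"]
  exclusion:
    ICD10: ["A187", "E273"]    # tuberculous / drug-induced adrenal failure
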