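{"label": "district health covariates", "spatial": "both",
 "inefficiency_terms": ["Spec", "MSStrDis", "NumStrHospDis", "PatShaStroke", "MedDepCon", "SUCert", "SUnonCert", "GPsPerDis", "HosBed", "PrivHos", "NonProfHos", "Teach", "UniHos", "ShaI61", "ShaI64", "DiagCon", "ShaTRHOMB", "MortalityDis", "PopageDis", "UnemplrateDis", "GDPpCapDis"]}
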