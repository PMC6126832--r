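{"label": "certificate age split", "spatial": "both",
 "inefficiency_terms": ["Spec", "MSStrDis", "NumStrHospDis", "PatShaStroke", "MedDepCon", "SUCert_young", "SUCert_old", "SUnonCert", "GPsPerDis", "HosBed", "PrivHos", "NonProfHos", "Teach", "UniHos", "ShaI61", "ShaI64", "DiagCon", "ShaTRHOMB"]}
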