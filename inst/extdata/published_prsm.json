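{
  "pairs": [
    {"irg1": "APBB1IP", "irg2": "SLA", "coefficient": 0.36},
    {"irg1": "SIGLEC10", "irg2": "KLRB1", "coefficient": 0.24},
    {"irg1": "NFAM1", "irg2": "SLA", "coefficient": 0.22},
    {"irg1": "FAM78A", "irg2": "SIRPG", "coefficient": 0.12},
    {"irg1": "FAM78A", "irg2": "CIITA", "coefficient": 0.33},
    {"irg1": "IL2RB", "irg2": "ODF3B", "coefficient": -0.46},
    {"irg1": "DOCK2", "irg2": "CXCR6", "coefficient": 0.20},
    {"irg1": "ARHGAP25", "irg2": "SLA", "coefficient": 0.23},
    {"irg1": "SLA", "irg2": "TAGAP", "coefficient": 0.57},
    {"irg1": "SLA", "irg2": "CXCL13", "coefficient": 0.05},
    {"irg1": "RHOH", "irg2": "TIGIT", "coefficient": 0.07},
    {"irg1": "TIGIT", "irg2": "APOBEC3H", "coefficient": -0.10},
    {"irg1": "TRIM22", "irg2": "SLFN5", "coefficient": -0.29},
    {"irg1": "PPP1R16B", "irg2": "GZMM", "coefficient": -0.23},
    {"irg1": "LY9", "irg2": "CLECL1", "coefficient": 0.46},
    {"irg1": "CXCL13", "irg2": "CD7", "coefficient": -0.18}
  ],
  "cutoff": 0.968,
  "provenance": "published 16-pair immune-related gene-pair risk model for left- vs right-sided colon adenocarcinoma (5-year ROC cutoff)"
}
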