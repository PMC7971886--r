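"reaction","mM_per_s"
"pts",0.0127664393856755
"glyt",0
"pfk",0.012766439385743
"gapdh",0.0255328787714859
"pyk",0.0125539041498248
"pdh",0.0253203435355677
"cs_icd",0.0253203435355164
"akgdh",0.0253203435355677
"ppc",0.000212535235918199
"oxphos",0.126814252913757
"pnt",0.0253203435355677
"oaa_sink",0.000212535235918199
"atpm",0.177454939984892
"ak",0
"feed_carbon",0.012766439385743
"drain_GLY",0
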