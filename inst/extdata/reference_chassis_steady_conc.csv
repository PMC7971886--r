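"species","mM"
"GLCx",2.82814587015893
"GLYx",0
"G6P",0.14440643451241
"DAP",0.113733034097164
"PEP",0.107959236076306
"PYR",0.130745308758827
"ACCOA",0.0455251460752246
"OAA",0.212535235918199
"AKG",0.0836735228696809
"GLY",0
"COA",1.45447485392477
"NAD",1.60277129616866
"NADH",0.047228703831328
"NADP",0.192101074059631
"NADPH",0.00789892594036798
"ATP",1.1003420109834
"ADP",1.13301003987813
"AMP",1.16664794913843
"Pi",33.2002072334692
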