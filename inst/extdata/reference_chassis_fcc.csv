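"reaction","fcc_structural","fcc_fd"
"pts",2.58825566059018e-15,2.63405971179194e-09
"glyt",0,0
"pfk",1.11238036004748e-16,6.37660249488464e-15
"gapdh",4.78043382051361e-16,7.14307011476977e-10
"pyk",-1.05182654186655,-1.05194251818735
"pdh",6.63190935012086e-19,0.00114416536251289
"cs_icd",-4.61666437993146e-15,0.000464588514879137
"akgdh",-1.54869261120102e-16,-3.18830124744232e-14
"ppc",0.982239696368132,0.982239729940159
"oxphos",-6.6246162703185e-14,0.00134235792856406
"pnt",4.46800669605076e-18,3.19946072266413e-06
"oaa_sink",3.44169137633799e-15,6.37660249488464e-15
"atpm",0.0065295204226991,0.00648800055859888
"ak",0,2.55064099795385e-14
"feed_carbon",1.06305732507585,1.06308539226637
"drain_GLY",0,0
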