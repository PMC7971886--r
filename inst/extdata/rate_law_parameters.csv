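table,reaction,mechanism,slot,value
native,G3pD,rapid_equilibrium_random_bibi_reversible,Km_a,0.175
native,G3pD,rapid_equilibrium_random_bibi_reversible,Km_b,0.0037
native,G3pD,rapid_equilibrium_random_bibi_reversible,Km_p,0.12
native,G3pD,rapid_equilibrium_random_bibi_reversible,Km_q,0.165
native,G3pD,rapid_equilibrium_random_bibi_reversible,Keq,900
native,G3pP,michaelis_menten_1s,Km,2.9
native,GlyK,mm_2s_random_bibi_denominator,Km_a,0.0084
native,GlyK,mm_2s_random_bibi_denominator,Km_b,0.0049
native,GlyK,mm_2s_random_bibi_denominator,Kd_a,0.086
native,AccC,ordered_bibi_product_inhibition,Km_a,0.018
native,AccC,ordered_bibi_product_inhibition,Km_b,0.06
native,AccC,ordered_bibi_product_inhibition,Ki_p,0.07
native,GluD,mm_2s_multiplicative,Km_a,0.495
native,GluD,mm_2s_multiplicative,Km_b,0.037
native,AspAT,ping_pong_bibi_reversible,Km_a,19.07
native,AspAT,ping_pong_bibi_reversible,Km_b,0.19
native,AspAT,ping_pong_bibi_reversible,Km_p,0.437
native,AspAT,ping_pong_bibi_reversible,Km_q,2.94
native,AspAT,ping_pong_bibi_reversible,Keq,3.2
native,AspC,michaelis_menten_1s,Km,0.155
native,GlyD,hill_2s,Km_a,47.83
native,GlyD,hill_2s,Km_b,1.385
native,GlyD,hill_2s,n,0.98
native,DhaPT,mass_action,k,NA
heterologous,GlyDH,specific_activation,Kcat,0.0621
heterologous,GlyDH,specific_activation,Km_a,6.15
heterologous,GlyDH,specific_activation,Ka,0.008
heterologous,3hpaD,mm_competitive_product_inhibition_2s,Kcat,16.73
heterologous,3hpaD,mm_competitive_product_inhibition_2s,Km_a,0.39
heterologous,3hpaD,mm_competitive_product_inhibition_2s,Km_b,1.3
heterologous,3hpaD,mm_competitive_product_inhibition_2s,Ki_p,0.12
heterologous,McoaR,mm_2s_random_bibi_denominator,Kcat,50
heterologous,McoaR,mm_2s_random_bibi_denominator,Km_a,0.3
heterologous,McoaR,mm_2s_random_bibi_denominator,Km_b,0.03
heterologous,MsaR,mm_2s_random_bibi_denominator,Kcat,115
heterologous,MsaR,mm_2s_random_bibi_denominator,Km_a,0.07
heterologous,MsaR,mm_2s_random_bibi_denominator,Km_b,0.07
heterologous,BaTA,ping_pong_bibi_substrate_inhibition,Kcat,47.4
heterologous,BaTA,ping_pong_bibi_substrate_inhibition,Km_a,5.8
heterologous,BaTA,ping_pong_bibi_substrate_inhibition,Km_b,1.07
heterologous,BaTA,ping_pong_bibi_substrate_inhibition,Ki_b,10.2
heterologous,3hpcoaS,mm_3s_multiplicative,Kcat,36
heterologous,3hpcoaS,mm_3s_multiplicative,Km_a,0.015
heterologous,3hpcoaS,mm_3s_multiplicative,Km_b,0.01
heterologous,3hpcoaS,mm_3s_multiplicative,Km_c,0.05
heterologous,3hpcoaDH,michaelis_menten_1s,Kcat,96
heterologous,3hpcoaDH,michaelis_menten_1s,Km,0.06
heterologous,AcoaTioE,michaelis_menten_1s,Kcat,0.55
heterologous,AcoaTioE,michaelis_menten_1s,Km,0.167
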