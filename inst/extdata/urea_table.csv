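# Urea-denaturation equilibrium parameters for NCBD variants (CD at
# 222 nm, 1 M TMAO, 10 C). "shared" columns come from a global fit with
# one m-value across all variants (m_shared = 0.61 +/- 0.05
# kcal mol^-1 M^-1); "free" columns from independent fits. Midpoints in
# M urea, m in kcal mol^-1 M^-1, dG in kcal/mol.
variant,urea50_shared,dG_shared,urea50_free,m_free,dG_free
D/P,2.4,1.5,2.2,0.56,1.2
D/P T2062I,3.3,2.0,3.4,0.70,2.4
1R/2R,4.4,2.7,4.4,0.67,3.0
Fish/tetrapod CREBBP,4.0,2.5,4.0,0.62,2.5
Hsa CREBBP,3.8,2.3,3.7,0.46,1.7
Hsa p300,4.4,2.7,4.4,0.66,2.9
Dre CREBBP1,3.4,2.1,2.2,0.33,0.7
Pma,4.1,2.5,4.2,0.50,2.1
Dmel,1.6,1.0,2.6,1.2,3.3
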