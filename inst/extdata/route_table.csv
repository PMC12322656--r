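route_id,enzymes,substrate,product,productivity_g_L_h,productivity_mM_h,ton_g_g,enzyme_loading_g_L,yield_pct,purity_pct,titer_mM,e_factor,auxiliaries
2,"YjjG, UP, DeoB, YeiN",UMP,Psi,18,74,22,9.0,80,80,800,3.4,Mn2+
1,"UP, DeoB, YeiN",U,PsiMP,30,93,74,4.3,97,95,970,2.4,Mn2+
4,"RbsK, AcK, YeiN","Rib, Ura",PsiMP,38,117,146,2.0,90,70,650,43,"ATP, AcP, Mg2+"
5,"RY, YeiN",UMP,PsiMP,294,906,103,3.0,95,95,950,3.0,Mn2+
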