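# Sterility QTL inventory for the two tomato-clade introgression-line
# crosses (SH x SL and SP x SL).  Structure, per-cross totals,
# co-localization links, confounding flags, and the effect sizes and
# dominance of the three co-localized loci follow the published mapping
# results; per-locus effect sizes and dominance of the cross-unique QTL are
# SYNTHETIC stand-ins (the per-locus supplements are not machine-readable)
# and no packaged analysis depends on them.
qtl_id,cross,trait,chromosome,delta_pct,dominance_D,colocal_partner,pollen_confounded
pf7.2_SHxSL,SHxSL,pollen,7,-39.3,-0.28,pf7.2_SPxSL,FALSE
pf1.1,SHxSL,pollen,1,-31.0,-0.55,NA,FALSE
pf2.1,SHxSL,pollen,2,-44.0,-0.70,NA,FALSE
pf4.1,SHxSL,pollen,4,-27.0,-0.45,NA,FALSE
pf8.1,SHxSL,pollen,8,-35.0,-0.60,NA,FALSE
pf9.1,SHxSL,pollen,9,-52.0,-0.80,NA,FALSE
pf11.1,SHxSL,pollen,11,-24.0,-0.40,NA,FALSE
pf12.1,SHxSL,pollen,12,-38.0,-0.65,NA,FALSE
pf7.2_SPxSL,SPxSL,pollen,7,-37.7,-0.28,pf7.2_SHxSL,FALSE
pf3.1p,SPxSL,pollen,3,-29.0,-0.50,NA,FALSE
pf5.1p,SPxSL,pollen,5,-41.0,-0.75,NA,FALSE
pf6.1p,SPxSL,pollen,6,-33.0,-0.55,NA,FALSE
pf9.1p,SPxSL,pollen,9,-47.0,-0.85,NA,FALSE
pf10.1p,SPxSL,pollen,10,-26.0,-0.35,NA,FALSE
pf12.1p,SPxSL,pollen,12,-36.0,-0.60,NA,FALSE
sss1.2_SHxSL,SHxSL,seed,1,-89.1,-0.39,sss1.2_SPxSL,FALSE
sss2.1_SHxSL,SHxSL,seed,2,-74.2,-0.71,sss2.1_SPxSL,TRUE
sss4.1,SHxSL,seed,4,-48.0,-0.50,NA,FALSE
sss6.1,SHxSL,seed,6,-61.0,-0.70,NA,FALSE
sss10.1,SHxSL,seed,10,-39.0,-0.45,NA,FALSE
sss1.2_SPxSL,SPxSL,seed,1,-82.9,-0.39,sss1.2_SHxSL,FALSE
sss2.1_SPxSL,SPxSL,seed,2,-62.5,-0.71,sss2.1_SHxSL,FALSE
sss3.1p,SPxSL,seed,3,-55.0,-0.60,NA,FALSE
sss8.1p,SPxSL,seed,8,-44.0,-0.50,NA,FALSE
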