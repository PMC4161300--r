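# Genotype fertility least-squares means and Tukey HSD letter groups from
# the three cross-species tests of allelism (seed loci in seeds/fruit;
# pollen locus in proportion fertile pollen).  Genotypes sharing a letter
# within a locus are statistically indistinguishable.
locus,trait,genotype,ls_mean,letters
sss1.2,seed,SL,60.83,A
sss1.2,seed,IL_PP,10.41,C
sss1.2,seed,IL_HH,38.13,B
sss1.2,seed,IL_HP,26.66,B
sss2.1,seed,SL,60.83,A
sss2.1,seed,IL_PP,11.08,B
sss2.1,seed,IL_HH,64.89,A
sss2.1,seed,IL_HP,67.93,A
pf7.2,pollen,SL,0.90,A
pf7.2,pollen,IL_PP,0.81,B
pf7.2,pollen,IL_HH,0.76,B
pf7.2,pollen,IL_HP,0.77,B
pf7.2,pollen,IL_PH,0.78,B
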