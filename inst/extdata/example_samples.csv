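individual_id,taxon_name,section,subsection,ploidy,accessions
allo01,sim_taxon_allo01,Malachobatus,,4,allo01__1;allo01__2
allo02,sim_taxon_allo02,Malachobatus,,4,allo02__1;allo02__2
auto01,sim_taxon_auto01,Malachobatus,,4,auto01__1;auto01__2
auto02,sim_taxon_auto02,Malachobatus,,4,auto02__1;auto02__2
dA01,sim_taxon_dA01,Idaeobatus,,2,dA01__1
dA02,sim_taxon_dA02,Idaeobatus,,2,dA02__1
dA03,sim_taxon_dA03,Idaeobatus,,2,dA03__1
dB01,sim_taxon_dB01,Idaeobatus,,2,dB01__1
dB02,sim_taxon_dB02,Idaeobatus,,2,dB02__1
dB03,sim_taxon_dB03,Idaeobatus,,2,dB03__1
OUT01,sim_taxon_OUT01,Outgroup,,2,OUT01__1
OUT02,sim_taxon_OUT02,Outgroup,,2,OUT02__1
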