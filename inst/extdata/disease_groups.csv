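disease_group,icd10_ranges,priority
infectious,A00-B99,2
neoplasms,C00-D49,2
blood_immune,D50-D89,2
diabetes,E10-E14,1
endocrine_metabolic,E00-E09;E15-E99,2
alzheimer_dementia,F00-F03;G30-G31.1;G31.8-G31.9,1
mental,F04-F99,2
nervous,G00-G99,2
eye,H00-H59,2
ear,H60-H95,2
circulatory,I00-I99,2
copd,J41-J44,1
respiratory,J00-J40;J45-J99,2
digestive,K00-K99,2
skin,L00-L99,2
musculoskeletal,M00-M99,2
urinary,N00-N39,2
reproductive,N40-N98,2
pregnancy,O00-O99,2
newborn,P00-P96;Q00-Q45,2
injuries,S00-S99;T08-T19;T33-T99;V01-V99;X01-X99;Y01-Y99,2
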