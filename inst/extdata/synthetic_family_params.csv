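family,species,Mi,Ri,calc_score,provenance
Capitellidae,Capitella sp.,2,4,0,species-scored
Capitellidae,Notomastus sp.,2,4,0,species-scored
Ampharetidae,Amphisamytha sp.,1,2,1,species-scored
Dorvilleidae,Ophryotrocha sp. A,3,2,0,species-scored
Dorvilleidae,Ophryotrocha sp. B,3,2,0,species-scored
Dorvilleidae,Parougia sp.,2,2,0,species-scored
Thyasiridae,Thyasira sp.,2,3,5,expert
Lucinidae,Lucinoma sp.,2,3,5,expert
Hyalidae,,3,1,2,expert
Cumacea_fam,,3,2,3,expert
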