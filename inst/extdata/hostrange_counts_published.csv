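phage,species,infected,tested,percent_printed,subgroup
CP68,all,31,255,12.2,CP220_subgroup
CP75,all,30,255,11.8,CP220_subgroup
CP84,all,34,255,13.3,CP220_subgroup
CP7,all,19,255,7.5,CP21_subgroup
CP83,all,15,255,5.9,CP21_subgroup
CP21,all,17,255,6.7,CP21_subgroup
IBB_35,all,12,90,13.3,CP220_subgroup
CP68,C. jejuni,21,227,9.3,CP220_subgroup
CP75,C. jejuni,20,227,8.8,CP220_subgroup
CP84,C. jejuni,24,227,10.6,CP220_subgroup
CP7,C. jejuni,14,227,6.2,CP21_subgroup
CP83,C. jejuni,13,227,5.7,CP21_subgroup
CP21,C. jejuni,13,227,5.7,CP21_subgroup
IBB_35,C. jejuni,5,76,6.6,CP220_subgroup
CP68,C. coli,10,18,55.6,CP220_subgroup
CP75,C. coli,10,18,55.6,CP220_subgroup
CP84,C. coli,10,18,55.6,CP220_subgroup
CP7,C. coli,5,18,27.8,CP21_subgroup
CP83,C. coli,2,18,11.1,CP21_subgroup
CP21,C. coli,4,18,22.2,CP21_subgroup
IBB_35,C. coli,7,14,50.0,CP220_subgroup
CP68,C. lari,0,5,0.0,CP220_subgroup
CP75,C. lari,0,5,0.0,CP220_subgroup
CP84,C. lari,0,5,0.0,CP220_subgroup
CP7,C. lari,0,5,0.0,CP21_subgroup
CP83,C. lari,0,5,0.0,CP21_subgroup
CP21,C. lari,0,5,0.0,CP21_subgroup
IBB_35,C. lari,0,5,0.0,CP220_subgroup
CP68,C. fetus,0,2,0.0,CP220_subgroup
CP75,C. fetus,0,2,0.0,CP220_subgroup
CP84,C. fetus,0,2,0.0,CP220_subgroup
CP7,C. fetus,0,2,0.0,CP21_subgroup
CP83,C. fetus,0,2,0.0,CP21_subgroup
CP21,C. fetus,0,2,0.0,CP21_subgroup
IBB_35,C. fetus,0,2,0.0,CP220_subgroup
CP68,C. sputorum,0,2,0.0,CP220_subgroup
CP75,C. sputorum,0,2,0.0,CP220_subgroup
CP84,C. sputorum,0,2,0.0,CP220_subgroup
CP7,C. sputorum,0,2,0.0,CP21_subgroup
CP83,C. sputorum,0,2,0.0,CP21_subgroup
CP21,C. sputorum,0,2,0.0,CP21_subgroup
IBB_35,C. sputorum,0,2,0.0,CP220_subgroup
CP68,C. hyointestinalis,0,1,0.0,CP220_subgroup
CP75,C. hyointestinalis,0,1,0.0,CP220_subgroup
CP84,C. hyointestinalis,0,1,0.0,CP220_subgroup
CP7,C. hyointestinalis,0,1,0.0,CP21_subgroup
CP83,C. hyointestinalis,0,1,0.0,CP21_subgroup
CP21,C. hyointestinalis,0,1,0.0,CP21_subgroup
IBB_35,C. hyointestinalis,0,1,0.0,CP220_subgroup
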