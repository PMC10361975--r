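sample_id,institution,year,visit_index,Age,Sex,HbA1c,Hb,FPG,CBG,RBC,UG,UP,HDLC,LDLC,AST,GGT,Scr,Hct
S01,clinic,2014,1,64,M,6.0,13.5,100,,,,(-),,,,,,
S01,clinic,2014,2,,,6.2,,110,,,,(+),,,,,,
S01,clinic,2015,1,65,M,6.3,13.6,104,,,,(-),,,,,,
S01,clinic,2017,1,,,6.5,,126,,,,,,,,,,
S02,clinic,2014,1,70,F,6.2,12.8,108,,,,(+-),,,,,,
S02,clinic,2015,1,71,F,6.4,12.9,112,,,,(+-),,,,,,
S02,clinic,2016,1,,,7.2,,150,,,,,,,,,,
S03,clinic,2014,1,55,M,5.6,14.0,98,,,,(-),,,,,,
S03,clinic,2015,1,56,M,5.7,,,,,,,,,,,,
S03,clinic,2016,1,,,6.4,,125,,,,,,,,,,
S03,clinic,2017,1,,,6.4,,125,,,,,,,,,,
S03,clinic,2018,1,,,6.4,,125,,,,,,,,,,
S04,clinic,2014,1,60,F,5.9,13.2,102,,,,(-),,,,,,
S04,clinic,2015,1,61,F,6.0,13.3,,,,,(-),,,,,,
S04,clinic,2016,1,,,7.0,,100,,,,,,,,,,
S04,clinic,2016,2,,,6.2,,160,,,,,,,,,,
S05,clinic,2014,1,48,M,5.4,15.0,95,,,,,,,,,,
S05,clinic,2015,1,49,M,5.5,,,,,,,,,,,,
S05,clinic,2018,1,,,5.5,,100,,,,,,,,,,
S06,clinic,2014,1,66,F,5.8,12.5,99,,,,(-),,,,,,
S06,clinic,2015,1,67,F,5.9,12.6,,,,,(-),,,,,,
S06,clinic,2016,1,,,5.8,,95,,,,,,,,,,
S07,clinic,2014,1,72,M,,13.9,,,,,(-),,,,,,
S07,clinic,2015,1,73,M,6.1,14.0,,,,,(-),,,,,,
S07,clinic,2017,1,,,6.0,,110,,,,,,,,,,
S08,clinic,2014,1,58,F,5.7,13.0,,,,,(-),,,,,,
S08,clinic,2015,1,,,,,120,,,,,,,,,,
S08,clinic,2016,1,,,6.2,,118,,,,,,,,,,
S09,clinic,2014,1,62,M,5.9,14.2,,,,,(-),,,,,,
S09,clinic,2015,1,63,M,6.0,14.3,,,,,(-),,,,,,
S09,clinic,2016,1,,,6.8,,,,,,,,,,,,
S09,clinic,2017,1,,,7.0,,,,,,,,,,,,
S10,clinic,2014,1,50,F,5.5,12.0,90,,,,(-),,,,,,
S10,clinic,2016,1,,,7.5,,170,,,,,,,,,,
S11,clinic,2015,1,45,M,5.6,14.8,92,,,,(-),,,,,,
S11,clinic,2017,1,,,7.4,,168,,,,,,,,,,
S12,clinic,2014,1,69,F,6.1,12.2,,,,,,,,,,,
S12,clinic,2015,1,,,,,,,,(+),,,,,,,
S12,clinic,2017,1,,,5.9,,105,,,,,,,,,,
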