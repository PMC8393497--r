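id,sex,age,pathology,molecular,met_pet,adc,samples_t1t2,samples_met,samples_adc
1,M,68,AA,IDH-wt,Performed,Performed,4,4,4
2,M,68,AA,IDH-wt,-,Performed,5,-,5
3,F,81,DA,IDH-wt,Performed,Performed,5,5,5
4,M,72,GBM,IDH-wt,-,Performed,3 (3),-,3 (3)
5,M,19,GBM,IDH-wt,-,-,4 (2),-,-
6,M,70,GBM,IDH-wt,-,-,6 (3),-,-
7,F,72,GBM,IDH-wt,-,Performed,1 (1),-,1 (1)
8,F,68,GBM,IDH-wt,Performed,Performed,2 (2),2 (2),2 (2)
9,M,52,GBM,IDH-wt,-,-,3 (2),-,-
10,M,76,GBM,IDH-wt,-,Performed,3 (2),-,3 (2)
11,F,34,GBM,IDH-wt,Performed,Performed,7 (6),7 (6),7 (6)
12,M,30,rec. AA,IDH-wt,-,-,3,-,-
13,F,45,rec. GBM,IDH-wt,-,Performed,3 (2),-,3 (2)
14,F,29,OL,"IDH-mt, 1p/19q-codeleted",Performed,Performed,6,6,6
15,F,48,OL,"IDH-mt, 1p/19q-codeleted",Performed,Performed,4,4,4
16,M,37,OL,"IDH-mt, 1p/19q-codeleted",Performed,Performed,-,-,-
17,M,30,OL,"IDH-mt, 1p/19q-codeleted",Performed,Performed,4,4,4
18,F,46,rec. AO,"IDH-mt, 1p/19q-codeleted",-,-,2 (2),-,-
19,M,48,rec. AO,"IDH-mt, 1p/19q-codeleted",Performed,Performed,3,3,3
20,F,35,AA,IDH-mt,-,Performed,5,-,6
21,M,34,DA,IDH-mt,Performed,Performed,4,4,4
22,F,48,DMG,H3 K27M-mt,-,Performed,1,-,1
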