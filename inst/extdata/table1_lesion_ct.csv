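patient_id,lesion_id,therapy,pfs_months,diameter_pre_cm,diameter_post_cm
1,1,Cisplatin/Platinol,4,4.4,1.8
2,1,Carboplatin/Paraplatin+Gemcitabine/Gemzar,NA,5.8,5.0
3,1,Erlotinib/Tarceva,21,1.9,0.7
4,1,Carboplatin/Paraplatin+Pemetrexed/Alimta,12,3.2,2.9
5,1,Cisplatin/Platinol+Gemcitabine/Gemzar,3,6.2,5.3
6,1,Cisplatin/Platinol+Pemetrexed/Alimta,14,2.1,1.7
7,1,Erlotinib/Tarceva,10,2.9,2.7
7,2,Erlotinib/Tarceva,10,2.5,2.1
8,1,Carboplatin/Paraplatin+Pemetrexed/Alimta,5,9.3,7.3
8,2,Carboplatin/Paraplatin+Pemetrexed/Alimta,5,1.4,0.8
9,1,Cisplatin/Platinol+Pemetrexed/Alimta,7,3.5,2.9
9,2,Cisplatin/Platinol+Pemetrexed/Alimta,7,2.8,1.6
9,3,Cisplatin/Platinol+Pemetrexed/Alimta,7,1.9,1.5
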