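snp_id	true_state	L1	L2	L3
snp1	00	0	0	0
snp2	11	0	0	1
snp3	01	0	1	0
snp4	10	1	0	0
snp5	00	0	0	0
snp6	00	0	0	0
snp7	00	0	0	0
snp8	00	0	0	0
snp9	00	0	0	0
snp10	10	1	0	0
snp11	00	0	0	0
snp12	11	0	0	1
snp13	00	0	0	0
snp14	01	0	1	0
snp15	00	0	0	0
snp16	00	0	0	0
snp17	00	0	0	0
snp18	00	0	0	0
snp19	00	0	0	0
snp20	00	0	0	0
snp21	00	0	0	0
snp22	01	0	1	0
snp23	00	0	0	0
snp24	11	0	0	1
snp25	10	1	0	0
snp26	00	0	0	0
snp27	00	0	0	0
snp28	00	0	0	0
snp29	00	0	0	0
snp30	00	0	0	0
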