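snp_id	A1	A2	A3	A4	A5	A6
snp1	1	0	0	0	0	0
snp2	0	0	0	0	1	1
snp3	0	0	1	1	0	0
snp4	1	1	0	0	0	0
snp5	1	0	0	0	0	0
snp6	0	0	0	0	0	0
snp7	0	0	1	0	0	0
snp8	0	0	0	0	0	1
snp9	0	0	0	1	0	0
snp10	1	1	0	0	0	0
snp11	0	0	0	1	0	0
snp12	0	0	0	0	1	1
snp13	0	0	0	0	1	0
snp14	0	0	1	1	0	0
snp15	0	1	0	0	0	0
snp16	0	0	0	0	0	1
snp17	1	0	0	0	0	0
snp18	0	1	0	0	0	0
snp19	0	0	0	0	1	0
snp20	0	0	0	0	1	0
snp21	0	0	0	0	0	0
snp22	0	0	1	1	0	0
snp23	0	0	0	1	0	0
snp24	0	0	0	0	1	1
snp25	1	1	0	0	0	0
snp26	0	0	0	0	0	0
snp27	0	0	1	0	0	0
snp28	0	0	0	0	0	1
snp29	0	0	1	0	0	0
snp30	0	1	0	0	0	0
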