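snp_id	p_trait1	p_trait2
snp1	0.3795592405	0.04298879602
snp2	0.0991551432	0.6359340443
snp3	0.03743103286	0.1602447261
snp4	0.2184852875	0.4793985642
snp5	0.4317512489	0.1974103423
snp6	0.9575765966	0.7193558377
snp7	0.8877549055	0.007884738734
snp8	0.6399787695	0.3754899646
snp9	0.9709666104	0.5144077083
snp10	0.1167667634	0.001570554217
snp11	0.3334272113	0.5816040025
snp12	0.02452662275	0.03650224139
snp13	0.3984854114	0.3590283059
snp14	0.7846927757	0.008740478571
snp15	0.03893649112	0.7758233626
snp16	0.7487953862	0.5636468416
snp17	0.6772768302	0.2337033986
snp18	0.1712643304	0.08998051635
snp19	0.2610879638	0.08561206493
snp20	0.5144129347	0.3052183695
snp21	0.6756072745	0.6674265147
snp22	0.9828171979	0.02062973598
snp23	0.7595442676	0.2085699569
snp24	0.2184360277	0.9692550317
snp25	0.1133460356	0.9256447486
snp26	0.1894739354	0.734094301
snp27	0.2712866147	0.3330719834
snp28	0.8281584852	0.5150633298
snp29	0.6932048204	0.7439746463
snp30	0.2405447396	0.61915924
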