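protein	atoms	amino_acids	amino_acid_types	C	N	O	S_position	P_position	spatial_structure	overall_printed
S100A11	0.9708	0.9083	0.5294	0.9704	0.8677	0.9226	0.8000	1.0000	0.7384	0.8102
RASEF	0.6557	0.6881	0.9412	0.9929	0.9497	0.9069	0.8000	1.0000	0.6515	0.8068
GCN4	0.6241	0.2752	0.8235	0.9615	0.9271	0.9972	0.8000	1.0000	0.6231	0.7624
FKBP	-0.0255	0.9817	0.7647	0.9655	0.9067	0.9589	1.0000	1.0000	0.5055	0.7334
CENP-B	0.1144	0.4587	0.7647	0.9478	0.9172	0.9488	1.0000	1.0000	0.5535	0.7312
S100A2	0.2032	0.8532	0.5882	0.9611	0.8015	0.8642	0.8000	1.0000	0.5756	0.7046
CIB	0.1034	0.0826	0.8235	0.9497	0.8854	0.9778	0.8000	1.0000	0.5765	0.7026
GPD1	-0.5864	0.6789	0.7647	0.9561	0.8754	0.9505	0.8000	1.0000	0.5905	0.6944
PAK1	0.1521	-0.0275	0.6471	0.9575	0.8543	0.9398	0.8000	1.0000	0.5647	0.6716
ACTN1	-0.2701	-0.3761	0.8235	0.9596	0.9004	0.9721	1.0000	1.0000	0.5902	0.6883
APC	0.9720	0.5046	1.0000	0.9902	0.8994	0.8022	0	1.0000	0.4929	0.6709
GP41	0.4489	0.4128	0.7647	0.9504	0.9527	0.9699	0	1.0000	0.4517	0.6166
S100A12	0.2007	0.8257	0.2941	0.9603	0.8809	0.9300	0	1.0000	0.5668	0.6058
MACF	-0.7944	-0.3578	0.5294	0.9641	0.8395	0.8972	0.8000	1.0000	0.4992	0.5691
MST3	-0.4866	-0.5963	0.2941	0.9407	0.8296	0.9467	0	1.0000	0.5876	0.4997
CHP1	-1.7798	0.1376	0.8824	0.9796	0.9118	0.9021	0	1.0000	0.4568	0.4969
S100A1	-1.5122	0.8532	0.8824	0.5230	0.4119	0.5927	1.0000	1.0000	0.3412	0.4923
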