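chrom	saanen_ungapped	saanen_gaps	saanen_telomere	ars1_ungapped	ars1_gaps	ars1_telomere
1	157026289	12	9940	157403278	10	0
2	136815899	4	0	136510747	8	0
3	122007170	4	0	120037984	11	0
4	121353546	4	0	120733315	7	0
5	119111638	5	0	119019111	12	0
6	118192308	2	13717	117637248	15	0
7	108721103	4	11502	108433436	8	5318
8	114262317	5	13891	112671558	11	0
9	92377540	1	7926	91568381	8	5195
10	102383334	7	14353	101087335	9	24448
11	106922721	12	16286	106224777	9	0
12	88153514	6	18575	87276782	18	0
13	83177721	5	6611	83032465	9	0
14	94829756	1	11734	94672533	8	0
15	83141260	4	11585	81900668	12	0
16	80964695	4	2424	79367392	12	0
17	73078104	0	10066	71136580	9	0
18	67211768	4	4767	67274927	20	469
19	62759990	3	12832	62516200	10	2180
20	72063028	4	14488	71782370	5	2421
21	70281929	3	5029	69423070	13	0
22	60513250	2	5029	60280842	8	0
23	52518510	6	18806	48866424	5	2053
24	62595921	1	8188	62310016	2	0
25	43127748	3	14990	42858159	14	0
26	51538664	1	16511	51421353	8	0
27	44839895	0	0	44708984	2	0
28	44621055	0	0	44672302	0	0
29	51316256	1	18141	51332371	13	0
X	142335304	37	5497	115936137	214	0
Y	9603805	24	5310	NA	NA	NA
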