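name	saanen_chrom	saanen_start	saanen_end	ars1_chrom	ars1_start	ars1_end	length	description
Region 1	5	99084275	101783455	5	98973162	101785323	2812161	Inverted
Region 2	7	9511868	14628369	7	9353868	13740007	4386139	Inverted
Region 3	11	103733339	106912333	11	103232270	106224990	2992720	Inverted
Region 4	17	61267	2700348	17	0	2620773	2620773	Inverted
Region 5	18	14220403	20470517	18	16211458	22469539	6258081	Inverted
Region 6	23	33110782	35437285	18	0	1987427	1987427	Incorrectly placed
Region 7	23	48920741	50832698	23	32018169	33927923	1909754	Incorrectly placed
Region 8	25	40139	1085452	25	34034345	35098278	1063933	Incorrectly placed
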