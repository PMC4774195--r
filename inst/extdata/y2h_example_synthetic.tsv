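# Synthetic two-way Y2H example table (generated, not experimental data)
bait	prey	xgal	his3
BD-ARF1	AD-ARF1	++	85 %
BD-ARF5	AD-ARF1	-?	34 %
BD-ARF7	AD-ARF1	-	30 %
BD-ARF16	AD-ARF1	-	16 %
BD-IAA2	AD-ARF1	-?	27 %
BD-IAA3	AD-ARF1	-?	16 %
BD-IAA8	AD-ARF1	-?	28 %
BD-IAA12	AD-ARF1	-	14 %
BD-IAA17	AD-ARF1	?	21 %
BD-IAA28	AD-ARF1	-	9 %
BD-ARF1	AD-ARF5	-?	42 %
BD-ARF5	AD-ARF5	+	130 %
BD-ARF7	AD-ARF5	+	127 %
BD-ARF16	AD-ARF5	+	103 %
BD-IAA2	AD-ARF5	-	7 %
BD-IAA3	AD-ARF5	?	13 %
BD-IAA8	AD-ARF5	?	13 %
BD-IAA12	AD-ARF5	+?	12 %
BD-IAA17	AD-ARF5	+	100 %
BD-IAA28	AD-ARF5	?	12 %
BD-ARF1	AD-ARF7	-	
BD-ARF5	AD-ARF7	+	78 %
BD-ARF7	AD-ARF7	?	
BD-ARF16	AD-ARF7	-	13 %
BD-IAA2	AD-ARF7	+	72 %
BD-IAA3	AD-ARF7	++	83 %
BD-IAA8	AD-ARF7	++	126 %
BD-IAA12	AD-ARF7	?	
BD-IAA17	AD-ARF7	-	14 %
BD-IAA28	AD-ARF7	+	101 %
BD-ARF1	AD-ARF16	-	14 %
BD-ARF5	AD-ARF16	+	110 %
BD-ARF7	AD-ARF16	-?	39 %
BD-ARF16	AD-ARF16	+++	85 %
BD-IAA2	AD-ARF16	+	101 %
BD-IAA3	AD-ARF16	+	115 %
BD-IAA8	AD-ARF16	-?	10 %
BD-IAA12	AD-ARF16	+?	12 %
BD-IAA17	AD-ARF16	++	61 %
BD-IAA28	AD-ARF16	-	32 %
BD-ARF1	AD-IAA2	-	10 %
BD-ARF5	AD-IAA2	+?	8 %
BD-ARF7	AD-IAA2	+	109 %
BD-ARF16	AD-IAA2	+++	116 %
BD-IAA2	AD-IAA2	-	9 %
BD-IAA3	AD-IAA2	-?	33 %
BD-IAA8	AD-IAA2	?	24 %
BD-IAA12	AD-IAA2	-?	32 %
BD-IAA17	AD-IAA2	-	11 %
BD-IAA28	AD-IAA2	+	60 %
BD-ARF1	AD-IAA3	?	37 %
BD-ARF5	AD-IAA3	-	9 %
BD-ARF7	AD-IAA3	+	95 %
BD-ARF16	AD-IAA3	+++	79 %
BD-IAA2	AD-IAA3	?	14 %
BD-IAA3	AD-IAA3	?	15 %
BD-IAA8	AD-IAA3	+	73 %
BD-IAA12	AD-IAA3	+?	10 %
BD-IAA17	AD-IAA3	-	10 %
BD-IAA28	AD-IAA3	++	98 %
BD-ARF1	AD-IAA8	?	7 %
BD-ARF5	AD-IAA8	-	8 %
BD-ARF7	AD-IAA8	++	113 %
BD-ARF16	AD-IAA8	-?	7 %
BD-IAA2	AD-IAA8	-	30 %
BD-IAA3	AD-IAA8	+++	99 %
BD-IAA8	AD-IAA8	-?	11 %
BD-IAA12	AD-IAA8	+++	109 %
BD-IAA17	AD-IAA8	-	16 %
BD-IAA28	AD-IAA8	-?	11 %
BD-ARF1	AD-IAA12	-	32 %
BD-ARF5	AD-IAA12	-	32 %
BD-ARF7	AD-IAA12	?	15 %
BD-ARF16	AD-IAA12	-	11 %
BD-IAA2	AD-IAA12	-	32 %
BD-IAA3	AD-IAA12	-	16 %
BD-IAA8	AD-IAA12	++	85 %
BD-IAA12	AD-IAA12	+++	88 %
BD-IAA17	AD-IAA12	-?	11 %
BD-IAA28	AD-IAA12	-	13 %
BD-ARF1	AD-IAA17	-?	7 %
BD-ARF5	AD-IAA17	+	94 %
BD-ARF7	AD-IAA17	+?	14 %
BD-ARF16	AD-IAA17	+++	68 %
BD-IAA2	AD-IAA17	-	30 %
BD-IAA3	AD-IAA17	-	33 %
BD-IAA8	AD-IAA17	-?	28 %
BD-IAA12	AD-IAA17	+?	7 %
BD-IAA17	AD-IAA17	+?	8 %
BD-IAA28	AD-IAA17	-	
BD-ARF1	AD-IAA28	-	12 %
BD-ARF5	AD-IAA28	?	
BD-ARF7	AD-IAA28	+++	96 %
BD-ARF16	AD-IAA28	-	13 %
BD-IAA2	AD-IAA28	+	89 %
BD-IAA3	AD-IAA28	+	93 %
BD-IAA8	AD-IAA28	-	40 %
BD-IAA12	AD-IAA28	+?	9 %
BD-IAA17	AD-IAA28	-	7 %
BD-IAA28	AD-IAA28	-?	29 %
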