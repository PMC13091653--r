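reaction	ec_reference	claire	theia	crxnfp
5-Fluorouracil + NADPH -> 5,6-dihydrofluorouracil + NADP+	1.3.1.2	1.16.1	1.3.1	1.3.1.2
5,6-Dihydrofluorouracil + H2O -> 2-fluoro-3-ureidopropionic acid + H+	3.5.2.2	1.3.7	3.5.2	3.5.2.2
2-Fluoro-3-ureidopropionic acid + H2O + H+ -> 3-amino-2-fluoropropanoic acid + NH4+ + CO2	3.5.1.6	5.1.3	3.5.1	3.5.1.6
3-Amino-2-fluoropropanoic acid + H2O -> 3-aminopropanoic acid + H+ + F-	3.8.1.2	3.5.1	3.2.1	3.8.1.3
Fluoroacetate + H2O -> glycolate + H+ + F-	3.8.1.3 AND 3.8.1.2	1.1.1	3.8.1	3.8.1.3
Difluoroacetate + H2O -> 2-fluoro-2-hydroxyacetate + H+ + F-	3.8.1.3 AND 3.8.1.2	1.1.1	3.1.1	3.8.1.3
(E)-2,3,5,5,5-pentafluoro-4-(trifluoromethyl)pent-2-enoic acid + ATP + CoA -> (E)-2,3,5,5,5-pentafluoro-4-(trifluoromethyl)pent-2-enoic acid CoA + AMP + diphosphate	6.2.1	1.16.1	2.3.1	6.2.1.-
(E)-2,3,4,4,5,5,6,6,6-nonafluorohex-2-enoic acid + ATP + CoA -> (E)-2,3,4,4,5,5,6,6,6-nonafluorohex-2-enoic acid CoA + AMP + diphosphate	6.2.1	1.16.1	2.3.1	6.2.1.-
(E)-2,3,4,4,5,5,6,6,7,7,8,8,8-tridecafluorooct-2-enoic acid + ATP + CoA -> (E)-2,3,4,4,5,5,6,6,7,7,8,8,8-tridecafluorooct-2-enoic acid CoA + AMP + diphosphate	6.2.1	1.16.1	2.3.1	6.2.1.-
(E)-caffeate + ATP + CoA -> (E)-caffeoyl-CoA + AMP + diphosphate	6.2.1	2.8.2	6.2.1	6.2.1.-
(E)-caffeoyl-CoA + oxidized [2Fe-2S]-[ferredoxin] + NADH -> hydrocaffeoyl-CoA + reduced [2Fe-2S]-[ferredoxin] + NAD+	1.3.1.108	5.1.3	1.3.1	1.3.1.108
5,5,6,6,6-Pentafluorohexanoic acid + ATP + CoA -> 5,5,6,6,6-pentafluorohexanoic acid CoA + AMP + diphosphate	6.2.1	1.16.1	2.3.1	6.2.1.40
3,3,3-Trifluoropropanoic acid + ATP + CoA -> 3,3,3-trifluoropropanoic acid CoA + AMP + diphosphate	6.2.1	5.1.3	6.2.1	6.2.1.40
5,5,5-Trifluoropentanoic acid + ATP + CoA -> 5,5,5-trifluoropentanoic acid CoA + AMP + diphosphate	6.2.1	2.1.1	2.3.1	6.2.1.40
4,5,5-Trifluoropent-4-enoic acid + ATP + CoA -> 4,5,5-trifluoropent-4-enoic acid CoA + AMP + diphosphate	6.2.1	1.16.1	2.3.1	6.2.1.40
4,4,5,5,5-Pentafluoropentanoic acid + ATP + CoA -> 4,4,5,5,5-pentafluoropentanoic acid CoA + AMP + diphosphate	6.2.1	1.16.1	2.3.1	6.2.1.40
(E)-2,3,5,5,5-pentafluoro-4-(trifluoromethyl)pent-2-enoic acid CoA + oxidized [2Fe-2S]-[ferredoxin] + NADH -> 2,3,5,5,5-pentafluoro-4-(trifluoromethyl)pentanoic acid CoA + reduced [2Fe-2S]-[ferredoxin] + NAD+	1.3.1.108	5.1.3	1.18.1	1.3.1.108
(E)-2,3,4,4,5,5,6,6,6-nonafluorohex-2-enoic acid CoA + oxidized [2Fe-2S]-[ferredoxin] + NADH -> 2,3,4,4,5,5,6,6,6-nonafluorohexanoic acid CoA + reduced [2Fe-2S]-[ferredoxin] + NAD+	1.3.1.108	5.1.3		1.3.1.108
(E)-4,6,6,6-tetrafluoro-5-(trifluoromethyl)hex-2-enoic acid CoA + oxidized [2Fe-2S]-[ferredoxin] + NADH -> 4,6,6,6-tetrafluoro-5-(trifluoromethyl)hexanoic acid CoA + reduced [2Fe-2S]-[ferredoxin] + NAD+	1.3.1.108	1.3.1		1.3.1.108
(E)-2,3,4,4,5,5,6,6,7,7,8,8,8-tridecafluorooct-2-enoic acid CoA + oxidized [2Fe-2S]-[ferredoxin] + NADH -> 2,3,4,4,5,5,6,6,7,7,8,8,8-tridecafluorooctanoic acid CoA + reduced [2Fe-2S]-[ferredoxin] + NAD+	1.3.1.108	5.1.3		1.3.1.108
Paracetamol + H2O -> 4-aminophenol + H+ + acetate	3.5.1.13	2.1.1	3.5.1	3.5.1.135
N,N-Diethyl-3-methylbenzamide (DEET) + H2O -> 3-methylbenzoic acid + H+ + diethylamine	3.5.1	6.3.4	3.1.1	
N,N-Dimethyl 4-chlorobenzamide + H2O -> 4-chlorobenzoic acid + H+ + dimethylamine	3.5.1	2.1.1	3.1.1	
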