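protein	accession	peptide	precursor_mz	precursor_charge	product_ion	product_index	product_charge	product_mz	observed_fold_change	detected	cys_modified
Proenkephalin-A	P01210	ELLQLSKPELPQDGTSTLR	1063.7	2	y6	6	1	634.4	2.57	TRUE	FALSE
Proenkephalin-A	P01210	ELLQLSKPELPQDGTSTLR	1063.7	2	y9	9	1	974.5	2.57	TRUE	FALSE
Proenkephalin-A	P01210	ELLQLSKPELPQDGTSTLR	1063.7	2	y12	12	1	1313.7	2.57	TRUE	FALSE
Isoform 1 of Extracellular matrix protein 1	Q16610	QHVVYGPWNLPQSSYSHLTR	790.9	3	y10	10	2	588.3	1.19	TRUE	FALSE
Isoform 1 of Extracellular matrix protein 1	Q16610	QHVVYGPWNLPQSSYSHLTR	790.9	3	y15	15	2	871.9	1.19	TRUE	FALSE
Isoform 1 of Extracellular matrix protein 1	Q16610	QHVVYGPWNLPQSSYSHLTR	790.9	3	y16	16	2	953.5	1.19	TRUE	FALSE
Secretogranin 2	P13521	IESQTQEEVR	610.1	2	y8	8	2	488.7	1.54	TRUE	FALSE
Secretogranin 2	P13521	IESQTQEEVR	610.1	2	y8	8	1	976.5	1.54	TRUE	FALSE
Secretogranin 2	P13521	VLEYLNQEK	568.6	2	y6	6	1	794.4	1.54	TRUE	FALSE
Secretogranin 2	P13521	VLEYLNQEK	568.6	2	y7	7	1	923.4	1.54	TRUE	FALSE
Insulin-like growth factor binding protein 7	Q16270	ITVVDALHEIPVK	478.9	3	y10	10	2	560.8	-3.38	TRUE	FALSE
Insulin-like growth factor binding protein 7	Q16270	ITVVDALHEIPVK	478.9	3	y11	11	2	610.4	-3.38	TRUE	FALSE
Insulin-like growth factor binding protein 7	Q16270	ITVVDALHEIPVK	478.9	3	y12	12	2	660.9	-3.38	TRUE	FALSE
Insulin-like growth factor binding protein 7	Q16270	AGAAAGGPGVSGVCVCK	746.9	2	y7	7	1	783.4	-3.38	TRUE	TRUE
Insulin-like growth factor binding protein 7	Q16270	AGAAAGGPGVSGVCVCK	746.9	2	y10	10	1	1036.5	-3.38	TRUE	TRUE
Insulin-like growth factor binding protein 7	Q16270	AGAAAGGPGVSGVCVCK	746.9	2	y12	12	1	1150.6	-3.38	TRUE	TRUE
Isoform 1 of CD166 antigen	Q13740	SSPSFSSLHYQDAGNYVCETA	NA	NA	NA	NA	NA	NA	NA	FALSE	TRUE
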