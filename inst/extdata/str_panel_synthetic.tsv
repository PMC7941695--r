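# Synthetic Y-STR reference panel: standard forensic locus names with
# representative motif compositions and synthetic self-consistent chrY
# coordinates. Not real genome coordinates; supply a curated panel TSV
# in the same schema for production use.
name	motifs	start_hg19	end_hg19	start_hg38	end_hg38	named
DYS19	TAGA*15	3050000	3050059	3250000	3250059	1
DYS385a	GAAA*14	3100000	3100055	3300000	3300055	1
DYS385b	GAAA*14	3150000	3150055	3350000	3350055	1
DYS389I	TCTG*3,TCTA*12	3200000	3200059	3400000	3400059	1
DYS389II	TCTG*5,TCTA*16	3250000	3250083	3450000	3450083	1
DYS390	TCTG*8,TCTA*11	3300000	3300075	3500000	3500075	1
DYS391	TCTA*11	3350000	3350043	3550000	3550043	1
DYS392	TAT*13	3400000	3400038	3600000	3600038	1
DYS393	AGAT*12	3450000	3450047	3650000	3650047	1
DYS437	TCTA*9,TCTG*5	3500000	3500055	3700000	3700055	1
DYS438	TTTTC*10	3550000	3550049	3750000	3750049	1
DYS439	AGAT*12	3600000	3600047	3800000	3800047	1
DYS448	AGAGAT*20	3650000	3650119	3850000	3850119	1
DYS456	AGAT*15	3700000	3700059	3900000	3900059	1
DYS458	GAAA*17	3750000	3750067	3950000	3950067	1
DYS635	TCTA*21	3800000	3800083	4000000	4000083	1
YGATAH4	TAGA*12	3850000	3850047	4050000	4050047	1
DYS481	CTT*22	3900000	3900065	4100000	4100065	1
DYS533	ATCT*12	3950000	3950047	4150000	4150047	1
DYS549	GATA*13	4000000	4000051	4200000	4200051	1
DYS570	TTTC*17	4050000	4050067	4250000	4250067	1
DYS576	AAAG*18	4100000	4100071	4300000	4300071	1
DYS643	CTTTT*11	4150000	4150054	4350000	4350054	1
YS001u	AGAT*6	4200000	4200023	4400000	4400023	0
YS002u	TCTA*8	4250000	4250031	4450000	4450031	0
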