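# Synthetic Y-STR haplogroup-prediction reference: per-haplogroup allele
# counts at a subset of Yfiler loci. Demonstration data only; supply a
# curated reference TSV in this schema for real prediction.
haplogroup	locus	allele	count
O2	DYS19	14	60
O2	DYS19	15	40
O2	DYS390	24	70
O2	DYS390	25	30
O2	DYS391	10	80
O2	DYS391	11	20
O2	DYS392	11	55
O2	DYS392	13	45
O2	DYS393	12	65
O2	DYS393	13	35
R1b	DYS19	14	30
R1b	DYS19	15	70
R1b	DYS390	23	60
R1b	DYS390	24	40
R1b	DYS391	10	25
R1b	DYS391	11	75
R1b	DYS392	13	80
R1b	DYS392	14	20
R1b	DYS393	13	85
R1b	DYS393	12	15
E1b	DYS19	13	50
E1b	DYS19	14	50
E1b	DYS390	21	65
E1b	DYS390	24	35
E1b	DYS391	9	40
E1b	DYS391	10	60
E1b	DYS392	11	70
E1b	DYS392	12	30
E1b	DYS393	13	55
E1b	DYS393	14	45
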