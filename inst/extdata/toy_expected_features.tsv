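gene_id	transcript_id	length	log10_length	gc_content	oe_aug	oe_uga	oe_uaa	oe_uag	oe_cg	oe_ug	oe_uu	oe_ua	uorf_present	n_zero_tri_oe
g01	t1	6	0.77815125038364363	0.33333333333333331	9.0000000000000036	4.5000000000000018	0.0000000000000000	0.0000000000000000	0.00000000000000000	3.0000000000000000	0	0.0000000000000000	0	2
g02	t1	9	0.95424250943932487	0.11111111111111110	6.7500000000000000	6.7500000000000000	1.1250000000000002	0.0000000000000000	0.00000000000000000	4.5000000000000000	0	0.7500000000000000	1	1
g03	t1	12	1.07918124604762489	0.50000000000000000	0.0000000000000000	0.0000000000000000	0.0000000000000000	0.0000000000000000	4.00000000000000000	0.0000000000000000	0	2.6666666666666665	0	4
g04	t1	22	1.34242268082220617	0.54545454545454541	2.4200000000000004	2.4200000000000004	3.8720000000000003	2.4200000000000004	0.68750000000000000	1.6499999999999999	0	1.7600000000000002	1	0
g05	t1	23	1.36172783601759284	0.60869565217391308	5.2900000000000000	5.2900000000000000	5.2900000000000000	5.2900000000000000	0.00000000000000000	2.3000000000000003	0	2.3000000000000003	1	0
g06	t1	12	1.07918124604762489	1.00000000000000000	0.0000000000000000	0.0000000000000000	0.0000000000000000	0.0000000000000000	0.66666666666666663	0.0000000000000000	0	0.0000000000000000	0	4
g07	t1	10	1.00000000000000000	0.29999999999999999	8.3333333333333339	8.3333333333333339	0.0000000000000000	0.0000000000000000	0.00000000000000000	3.3333333333333335	0	0.0000000000000000	0	2
g10	t1	22	1.34242268082220617	0.54545454545454541	2.4200000000000004	2.4200000000000004	3.8720000000000003	2.4200000000000004	0.68750000000000000	1.6499999999999999	0	1.7600000000000002	1	0
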