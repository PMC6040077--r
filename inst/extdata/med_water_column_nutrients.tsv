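sample_id	depth_m	season	temperature_C	chlorophyll_mg_m3	oxygen_mg_L	TOC_mgC_L	PO4_uM	total_p_uM	NOx_uM	NH4_uM	total_n_uM	np_ratio_printed	total_bp_Gb	mean_read_length_bp	mean_gc_percent
MedWinter-JAN2015-20m	20	mixed	14.50	0.46	9.59	1.23	0.12	0.15	3.26	0.13	3.68	23.81	15.9	92	40.7
MedWinter-JAN2015-80m	80	mixed	14.40	0.21	9.42	1.03	0.08	0.12	3.89	0.11	4.36	35.74	15.3	91.9	41.1
Med-OCT2015-15m	15	stratified	22.90	0.10	7.09	2.43	0.06	0.10	0.20	0.13	0.40	4.00	19.9	121.4	38.6
Med-OCT2015-30m	30	stratified	18.40	0.24	8.77	2.17	0.07	0.12	0.21	0.12	0.41	3.42	15.1	117.2	41.4
Med-OCT2015-45m	45	stratified	15.80	0.78	9.00	1.46	0.10	0.14	0.25	0.14	0.48	3.43	3.1	112.3	40.4
Med-OCT2015-60m	60	stratified	14.50	0.36	7.66	1.43	0.08	0.12	0.23	0.15	0.46	3.83	15.3	119.8	40.6
Med-OCT2015-75m	75	stratified	14.00	0.26	7.16	1.36	0.12	0.16	5.79	0.09	6.33	39.56	16.9	121.4	41.3
Med-OCT2015-90m	90	stratified	13.80	0.08	6.88	1.35	0.22	0.25	6.23	0.08	6.90	27.60	15.0	120.2	41.1
Med-OCT2015-1000m	1000	stratified	13.10	0.01	6.10	0.84	0.39	0.45	8.24	0.03	8.89	19.76	14.8	117.0	45.9
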