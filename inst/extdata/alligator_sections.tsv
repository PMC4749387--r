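specimen_id	articulation	tissue	area_um2	length_um	skull_length_cm	maturity_rank	printed_width_um	printed_normalized_x1e3
MOR OST 1647	frontoparietal	suture	83871	681	2.5	1	123	4.92
MOR OST 1797	frontoparietal	suture	870966	7051	15.5	2	123	0.93
MOR OST 1798	frontoparietal	suture	6412890	30749	28.5	3	209	0.73
MOR OST 1647	internasal	suture	25806	290	2.5	1	89	3.56
MOR OST 1797	internasal	suture	225806	1737	15.5	2	130	0.84
MOR OST 1798	internasal	suture	1070966	4811	28.5	3	223	0.78
MOR OST 1647	basioccipital-exoccipital	synchondrosis	N/A	N/A	2.5	1	N/A	N/A
MOR OST 1797	basioccipital-exoccipital	synchondrosis	406451	4638	15.5	2	87	0.56
MOR OST 1798	basioccipital-exoccipital	synchondrosis	1445158	9931	28.5	3	145	0.51
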