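specimen_id	species	skull_length_cm	estimated_age	category	maturity_rank
MOR OST 1799	Dromaius novaehollandiae	5.5	a few weeks	juvenile	1
MOR OST 1801	Dromaius novaehollandiae	12.8	8 to 10 months	juvenile	2
MOR OST 1803	Dromaius novaehollandiae	15.2	20 years	skeletally_mature	3
MOR OST 1647	Alligator mississippiensis	2.5	a few days	juvenile	1
MOR OST 1797	Alligator mississippiensis	15.5	4-5 years	subadult	2
MOR OST 1798	Alligator mississippiensis	28.5	9-12 years	sexually_mature	3
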