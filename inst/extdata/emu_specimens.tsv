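specimen_id	skull_length_mm	age	sex	category
ROM R7945	54.00 (e)	A few weeks (?)		juvenile
MOR OST 1799	54.99	A few weeks (?)		juvenile
ROM R7644	55.00 (e)	A few weeks (?)		juvenile
MOR OST 1805	55.82	A few weeks		juvenile
ROM R7630	61.00 (e)	A few weeks (?)		juvenile
MOR OST 1806	62.27	A few weeks		juvenile
MOR OST 1807	63.08	A few weeks		juvenile
MOR OST 1800	97.07	A few months (?)		subadult
MOR-OST-1298	100.00 (e)	A few months (?)		subadult
MOR OST 1808	116.67	8 to 10 months		subadult
MOR OST 1802	128.36	A few months (?)		subadult
MOR OST 1809	149.11	8 to 10 months		subadult
MOR OST 1810	143.94	18 months		skeletally_mature
MOR OST 1814	151.9	18 months		skeletally_mature
MOR OST 1815	153.13	18 months		skeletally_mature
MOR OST 1811	154.39	18 months		skeletally_mature
MOR OST 1813	154.54	18 months		skeletally_mature
MOR OST 1297	155.00 (e)	> 10 months (?)		skeletally_mature
MOR OST 186	155.00 (e)	> 10 months (?)		skeletally_mature
MOR OST 1812	157.9	18 months		skeletally_mature
MOR OST1803	152.23	20 years	M	sexually_mature
MOR OST 232	158.17	> 18 months (?)		sexually_mature
ROM R6843	163	> 18 months (?)		sexually_mature
ROM R7654	166	> 18 months (?)		sexually_mature
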