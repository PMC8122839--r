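participant	device	line	mark
S01	custom	1	2
S01	custom	2	6
S01	custom	3	3
S01	custom	4	5
S01	custom	5	1
S01	custom	6	5
S01	custom	7	1
S01	generic	1	3
S01	generic	2	4
S01	generic	3	3
S01	generic	4	5
S01	generic	5	2
S01	generic	6	3
S01	generic	7	5
S02	custom	1	1
S02	custom	2	7
S02	custom	3	1
S02	custom	4	7
S02	custom	5	2
S02	custom	6	5
S02	custom	7	1
S02	generic	1	3
S02	generic	2	5
S02	generic	3	4
S02	generic	4	3
S02	generic	5	5
S02	generic	6	5
S02	generic	7	2
S03	custom	1	1
S03	custom	2	5
S03	custom	3	1
S03	custom	4	5
S03	custom	5	1
S03	custom	6	6
S03	custom	7	3
S03	generic	1	3
S03	generic	2	6
S03	generic	3	4
S03	generic	4	4
S03	generic	5	5
S03	generic	6	5
S03	generic	7	5
S04	custom	1	2
S04	custom	2	5
S04	custom	3	2
S04	custom	4	6
S04	custom	5	1
S04	custom	6	7
S04	custom	7	1
S04	generic	1	2
S04	generic	2	4
S04	generic	3	2
S04	generic	4	4
S04	generic	5	4
S04	generic	6	5
S04	generic	7	3
S05	custom	1	2
S05	custom	2	6
S05	custom	3	2
S05	custom	4	7
S05	custom	5	2
S05	custom	6	6
S05	custom	7	2
S05	generic	1	3
S05	generic	2	3
S05	generic	3	2
S05	generic	4	5
S05	generic	5	2
S05	generic	6	3
S05	generic	7	3
S06	custom	1	1
S06	custom	2	7
S06	custom	3	3
S06	custom	4	7
S06	custom	5	3
S06	custom	6	6
S06	custom	7	3
S06	generic	1	2
S06	generic	2	6
S06	generic	3	2
S06	generic	4	3
S06	generic	5	5
S06	generic	6	4
S06	generic	7	5
S07	custom	1	3
S07	custom	2	6
S07	custom	3	3
S07	custom	4	6
S07	custom	5	1
S07	custom	6	6
S07	custom	7	2
S07	generic	1	5
S07	generic	2	6
S07	generic	3	2
S07	generic	4	4
S07	generic	5	4
S07	generic	6	5
S07	generic	7	5
S08	custom	1	2
S08	custom	2	5
S08	custom	3	2
S08	custom	4	6
S08	custom	5	1
S08	custom	6	5
S08	custom	7	3
S08	generic	1	3
S08	generic	2	5
S08	generic	3	4
S08	generic	4	5
S08	generic	5	2
S08	generic	6	4
S08	generic	7	2
S09	custom	1	1
S09	custom	2	7
S09	custom	3	1
S09	custom	4	6
S09	custom	5	3
S09	custom	6	5
S09	custom	7	2
S09	generic	1	3
S09	generic	2	4
S09	generic	3	5
S09	generic	4	6
S09	generic	5	5
S09	generic	6	3
S09	generic	7	3
S10	custom	1	3
S10	custom	2	6
S10	custom	3	1
S10	custom	4	7
S10	custom	5	3
S10	custom	6	7
S10	custom	7	1
S10	generic	1	4
S10	generic	2	4
S10	generic	3	3
S10	generic	4	3
S10	generic	5	5
S10	generic	6	5
S10	generic	7	5
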