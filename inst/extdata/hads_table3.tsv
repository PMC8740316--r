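id	group	anxiety_score	depression_score
patient1	patient	7	7
patient2	patient	4	5
patient3	patient	6	6
patient4	patient	9	9
patient5	patient	8	8
patient6	patient	11	10
patient7	patient	10	10
patient8	patient	7	7
patient9	patient	12	11
patient10	patient	8	8
patient11	patient	8	8
patient12	patient	11	10
patient13	patient	7	6
patient14	patient	8	7
patient15	patient	13	12
patient16	patient	5	6
patient17	patient	8	9
hc1	control	3	2
hc2	control	3	2
hc3	control	3	2
hc4	control	3	1
hc5	control	4	3
hc6	control	4	2
hc7	control	3	2
hc8	control	1	2
hc9	control	1	1
hc10	control	1	2
hc11	control	3	3
hc12	control	3	2
hc13	control	2	2
hc14	control	3	2
hc15	control	5	3
hc16	control	3	1
hc17	control	4	3
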