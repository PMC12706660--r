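outlet	baseline	fa40	fa40_variation	aa40	aa40_variation	fa60	fa60_variation	aa60	aa60_variation
Right subclavian artery	3.0	2.8	-0.2	3.2	0.2	2.6	-0.4	3.7	0.7
Right common carotid artery	7.3	7.0	-0.3	7.2	-0.1	6.6	-0.7	7.1	-0.2
Left common carotid artery	4.3	4.4	0.1	4.6	0.3	4.2	-0.1	4.9	0.6
Left subclavian artery	9.2	9.3	0.1	10.1	0.9	9.0	-0.2	10.3	1.1
Right internal iliac artery	3.9	3.6	-0.3	3.8	-0.1	3.2	-0.7	3.7	-0.2
Left internal iliac artery	3.9	3.6	-0.3	3.8	-0.1	3.3	-0.6	3.7	-0.3
Right profunda femoris artery	5.3	4.9	-0.4	4.9	-0.4	4.4	-0.9	4.7	-0.6
Right femoral artery	6.1	9.6	3.5	5.3	-0.8	15.3	9.2	5.0	-1.1
Left profunda femoris artery	5.4	4.8	-0.6	5.0	-0.4	4.3	-1.1	4.7	-0.7
Left femoral artery	5.5	4.9	-0.6	5.1	-0.4	4.4	-1.1	4.8	-0.7
Inferior mesenteric artery	0.9	0.9	0.0	0.5	-0.4	0.8	-0.1	0.9	0.0
Superior mesenteric artery	11.0	10.4	-0.6	10.9	-0.1	9.6	-1.4	10.7	-0.3
Celiac trunk	15.4	14.8	-0.6	15.5	0.1	13.9	-1.5	15.5	0.1
Left renal artery	9.5	9.5	0.0	10.0	0.5	9.1	-0.4	10.2	0.7
Right renal artery	9.3	9.5	0.2	10.0	0.7	9.3	0.0	10.3	1.0
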