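subject	mriLh	histLh	mriRh	histRh
126	71.4	66	79.1	NA
127	NA	71.7	NA	NA
128	94.7	90.3	86.2	NA
129	88.5	81.6	83.6	NA
130	NA	68.8	NA	65.1
131	94.1	89.3	82.3	NA
132	69.2	NA	74.6	NA
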