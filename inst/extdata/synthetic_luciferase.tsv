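construct	replicate	fluc	rluc
with_stop	R1	7306.6577879584	105762.067758888
with_stop	R2	9181.69122663128	98282.9013280167
with_stop	R3	7735.28571271815	98419.5232269151
with_stop	R4	6117.05707447138	97532.5407789758
with_stop	R5	9489.58454198639	112648.142214123
with_stop	R6	5626.61362117483	84852.4597150385
no_stop	R1	52118.317618679	88665.3103747182
no_stop	R2	67683.4827715286	94760.2909126594
no_stop	R3	67815.4415190418	94638.9146090663
no_stop	R4	58312.6401858224	98530.4472803275
no_stop	R5	73893.4931896924	94924.7080376534
no_stop	R6	57438.6027263392	85516.6104040973
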