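code	1C_bp	ploidy	run_reads
VSA	1770000000	2	1050158
VVL	2040000000	2	2671672
VLT	2430000000	2	4812664
VCR	5800000000	4	6292470
VTS	3050000000	2	7873852
VSP	3740000000	2	1897538
VGR	3780000000	2	3289836
VHR	3880000000	2	6606736
VER	4060000000	2	4593996
VUN	4370000000	2	7201796
VPN	5730000000	2	2101204
VPF	6150000000	2	4460146
VNR	6690000000	2	3588026
VSL	6980000000	2	4883944
VML	8070000000	2	3595696
VPR	8450000000	2	6197134
VFB	13410000000	2	3192982
LNS	4290000000	2	5854630
LAV	5910000000	2	6632676
LAS	6520000000	2	3308288
LAL	9980000000	2	3091852
PST	4360000000	2	4525544
PFL	4690000000	2	5015824
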