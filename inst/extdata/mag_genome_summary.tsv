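id	origin	material	completeness	contamination	length_bp	aai_to_type_strain	ani_to_type_strain
MAG12a	Andreiasu	MAG	86.9	4.8	2729405	69.7	76.2
MAG19a	Andreiasu	MAG	99.4	1.3	3815928	79.5	82.7
MAG22a	Andreiasu	MAG	78.4	3.8	3341519	78.2	82.6
MAG26a	Andreiasu	MAG	98.9	0.9	4339169	77.4	85.4
MAG27a	Andreiasu	MAG	78.5	4.1	3487664	77.2	83.8
MAG32a	Andreiasu	MAG	97.1	1.4	3163398	62.0	72.6
MAG33a	Andreiasu	MAG	82.5	1.3	4651566	52.9	75.5
MAG2p	PipeCreek	MAG	89.8	1.9	4093978	70.6	78.3
MAG14p	PipeCreek	MAG	98.7	0.2	3486745	77.4	81.5
MAG15p	PipeCreek	MAG	85.9	2.2	2934464	68.8	80.8
MAG16p	PipeCreek	MAG	94.9	2.2	3860394	68.6	78.6
MAG17p	PipeCreek	MAG	82.4	0.5	2824381	73.7	80.7
MAG18p	PipeCreek	MAG	96.7	0.9	3990415	74.9	80.2
MAG38p	PipeCreek	MAG	87.7	2.4	3944496	79.6	81.6
MAG39p	PipeCreek	MAG	91.0	2.7	3229017	74.7	84.6
MAG47p	PipeCreek	MAG	95.7	1.1	3555802	56.2	77.2
MAG49p	PipeCreek	MAG	70.7	0.0	3567447	58.7	79.0
PC2	PipeCreek	WGS	98.3	0.8	4345403	68.6	79.3
PC3	PipeCreek	WGS	97.9	1.7	4316956	68.4	79.3
ANDR5	Andreiasu	WGS	99.8	4.1	4050246	79.5	82.6
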