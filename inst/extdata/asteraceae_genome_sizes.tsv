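species	mitogenome_bp	plastome_bp	gc_percent	n_pcgs	size_difference_printed
Lactuca sativa	363324	152765	45.35	32	210559
Diplostephium hartwegii	277718	151994	44.89	35	125724
Chrysanthemum boreale	211002	151012	45.36	35	59990
Chrysanthemum indicum	208097	150972	45.41	33	57125
Artemisia giraldii	194298	151072	45.66	32	43226
Ageratum conyzoides	219198	151325	45.4	30	67873
Helianthus grosseserratus	273543	151017	45.06	31	122526
Helianthus annuus	300945	151104	45.05	27	149841
Helianthus tuberosus	281287	151047	45.21	32	130240
Helianthus strumosus	281056	151044	45.37	32	130012
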