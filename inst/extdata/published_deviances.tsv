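cohort	classification	nested_model	full_model	minus2LL_nested	minus2LL_full	df	printed_p
aged	minor	E	ACE	1460.62	1446.58	2	8.9e-4
aged	minor	CE	ACE	1447.58	1446.58	1	0.32
aged	major	E	ADE	478.03	475.27	2	0.25
aged	two	E	ACE	1690.12	1655.41	2	2.9e-8
aged	three	CE	ACE	1916.14	1912.56	1	0.06
te	major	CE	ACE	5735.63	5717.52	1	2.1e-5
te	major	E	ACE	5813.19	5717.52	2	1.7e-21
te	two	E	ACE	6445.22	6353.91	2	1.5e-20
te	three	E	ACE	8381.43	8281.43	2	1.9e-22
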