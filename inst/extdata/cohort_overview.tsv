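# Per-study, per-disease-state participant and MAG totals for the five
# public colorectal-cancer stool metagenome cohorts, as published.
study	disease_state	n_participants	n_mags
Feng	healthy	61	1690
Feng	adenoma	47	1421
Feng	carcinoma	46	1418
Hannigan	healthy	26	101
Hannigan	adenoma	23	57
Hannigan	carcinoma	26	78
Vogtmann	healthy	58	1863
Vogtmann	adenoma	0	0
Vogtmann	carcinoma	52	1622
Yu	healthy	54	1397
Yu	adenoma	0	0
Yu	carcinoma	75	1910
Zeller	healthy	66	1839
Zeller	adenoma	42	956
Zeller	carcinoma	91	2584
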