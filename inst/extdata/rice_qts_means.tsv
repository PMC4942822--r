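trait	strategy	mean
PH	GWA	81.55
PH	QBA	81.40
PH	GBA	80.61
HD	GWA	98.49
HD	QBA	98.33
HD	GBA	99.46
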