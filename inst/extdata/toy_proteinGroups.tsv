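Protein IDs	Peptides	Potential contaminant	LFQ intensity probe_1	LFQ intensity probe_2	LFQ intensity probe_3	LFQ intensity probe_4	LFQ intensity control_1	LFQ intensity control_2	LFQ intensity control_3	LFQ intensity control_4
KEEP1	5		1024	2048	1024	1024	32	32	64	32
KEEP2	3		4096	4096	8192	4096	0	0	0	0
LOWPEP	2		1024	1024	1024	1024	64	64	64	64
CONT	10	+	1024	1024	1024	1024	64	64	64	64
PARTIAL	8		1024	1024	1024	0	64	64	64	0
KEEP3	4		512	512	0	0	128	128	128	128
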