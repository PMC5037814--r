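species	isoform	glyco_asn	phospho_sites	note
bovine	Casq1	316		skeletal isoform; C-terminal tail not phosphorylated
mouse	Casq1	316		skeletal isoform; C-terminal tail not phosphorylated
rat	Casq1	316		skeletal isoform; C-terminal tail not phosphorylated
bovine	Casq2	316	373,381	cardiac isoform; 0-2 phosphoryls observed
human	Casq2	316	366,374	cardiac isoform; 0-2 phosphoryls observed
rat	Casq2	316	379,386	cardiac isoform; 0-2 phosphoryls observed
canine	Casq2	316	NA	three C-terminal serines reported; exact numbering not curated here
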