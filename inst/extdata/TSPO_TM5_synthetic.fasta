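>TSPO_TM5_synthetic synthetic translocator-protein TM5 region; motif anchors at published coordinates (R135/Y138; V149-Y152-R156), remainder anchor-free filler
MAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGS
TLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPVMAGSTLPV
MAGSTLPVMSPLAARLLYPYLAWLAFTTVLNYYVWRDNHGGASTLPGVA
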