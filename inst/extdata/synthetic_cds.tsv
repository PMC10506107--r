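# coordinates are 0-based, half-open
transcript_id	cds_start	cds_end
synthetic_tx_long	90	336
synthetic_tx_short	90	255
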