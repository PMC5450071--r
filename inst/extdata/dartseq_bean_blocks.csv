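n_blocks,snps_in_blocks,total_span_kb,genome_kb
437,4354,368041.88,513589.10
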