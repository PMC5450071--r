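class,count
transition,3299
transversion,2655
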