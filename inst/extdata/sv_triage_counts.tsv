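# Structural-variant triage bookkeeping, as published: 551 predicted candidates
# from four detection methods; 470 dismissed on visual inspection as paired-end
# mapping errors; of the 81 retained, 38 were reference errors and 43 validated.
key	count
predicted	551
false_pe_error	470
reference_error	38
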