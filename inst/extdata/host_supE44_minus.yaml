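# Non-suppressing host (MC1061-like): amber clones escape the display
# burden and enrich over growth
supE44: no
display_burden: 0.1
generations: 19
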