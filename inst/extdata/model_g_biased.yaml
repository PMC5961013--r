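# Equimolar stock with a G incorporation advantage (efficiencies whose
# exact corrective is the stock mix N = G:1.0, A:1.5, T:1.5, C:1.6 and
# K = G:1.0, T:1.5)
stock_n: {A: 1.0, C: 1.0, G: 1.0, T: 1.0}
stock_k: {G: 1.0, T: 1.0}
efficiency: {A: 0.6667, C: 0.625, G: 1.0, T: 0.6667}
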