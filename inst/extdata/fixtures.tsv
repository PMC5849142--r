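# Named compounds of the chemoenzymatic HS/heparin oligosaccharide library.
# flag "printed": structure stated explicitly in the source text.
# flag "reconstructed": structure inferred from the synthesis-route logic
#   (scheme drawings / figure panels); see package vignette.
# columns: name <TAB> flag <TAB> sequence
seed	printed	GlcA-pNA-N3
I	reconstructed	GlcA(1-4)GlcNAc(1-4)GlcA(1-4)GlcNAc(1-4)GlcA-pNA-N3
II	reconstructed	GlcA(1-4)GlcNS(1-4)GlcA(1-4)GlcNAc(1-4)GlcA-pNA-N3
III	reconstructed	GlcA(1-4)GlcNS(1-4)GlcA-pNA-N3
IV	printed	GlcA(1-4)GlcNS(1-4)GlcA(1-4)GlcNS(1-4)GlcA-pNA-N3
V	printed	GlcA(1-4)GlcNS(1-4)IdoA(1-4)GlcNS(1-4)GlcA-pNA-N3
VI	printed	GlcA(1-4)GlcNS(1-4)IdoA2S(1-4)GlcNS(1-4)GlcA-pNA-N3
VII	reconstructed	GlcA(1-4)GlcNS(1-4)GlcA(1-4)GlcNS(1-4)GlcA(1-4)GlcNS(1-4)GlcA-pNA-N3
14	printed	GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3
28	reconstructed	GlcA(1-4)GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3
46	reconstructed	GlcNS6S(1-4)GlcA(1-4)GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3
65	reconstructed	GlcA(1-4)GlcNS(1-4)GlcA2S(1-4)GlcNS(1-4)GlcA-pNA-N3
66	reconstructed	GlcA2S(1-4)GlcNS(1-4)GlcA2S(1-4)GlcNS(1-4)GlcA-pNA-N3
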