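# Anomeric 1H/13C chemical shift model, version 1 (D2O, 298 K).
# Context is the residue on the REDUCING side of the predicted residue
# (the non-reducing neighbor has minimal influence and is ignored):
#   GlcA-neighbor  = gluco-uronic neighbor (GlcA, GlcA2S)
#   IdoA-neighbor  = ido-uronic neighbor (IdoA, IdoA2S)
#   GlcNX-neighbor / GlcNX6S-neighbor = N-acetyl or N-sulfo glucosamine
#       neighbor without / with a 6-O-sulfo group
#   aglycone-pNA   = reducing-terminal GlcA linked to the pNA-N3 tag
#       (aromatic-ring deshielding)
# Empty delta_c: no 13C value established; never imputed.
residue,context,delta_h,tol_h,delta_c,tol_c
GlcNS,GlcA-neighbor,5.52,0.04,97.0,0.2
GlcNS,IdoA-neighbor,5.24,0.02,97.3,0.2
GlcNS6S,GlcA-neighbor,5.52,0.04,97.1,0.2
GlcNS6S,IdoA-neighbor,5.33,0.02,96.2,0.2
GlcNS3S6S,IdoA-neighbor,5.43,0.04,96.0,0.2
GlcNAc,GlcA-neighbor,5.32,0.03,96.8,0.3
GlcNAc6S,GlcA-neighbor,5.33,0.02,96.7,0.3
GlcA,GlcNX-neighbor,4.43,0.05,102.0,0.5
GlcA,GlcNX6S-neighbor,4.54,0.05,,
GlcA,aglycone-pNA,5.07,0.05,,
GlcA2S,GlcNX-neighbor,4.65,0.05,100.1,0.5
GlcA2S,GlcNX6S-neighbor,4.65,0.05,100.1,0.5
IdoA,GlcNX-neighbor,4.95,0.05,101.5,0.5
IdoA,GlcNX6S-neighbor,4.95,0.05,101.5,0.5
IdoA2S,GlcNX-neighbor,5.18,0.05,99.0,0.5
IdoA2S,GlcNX6S-neighbor,5.18,0.05,99.0,0.5
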