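# Hand-computed per-residue mass increments (Da): mass of the residue as
# it sits inside a chain (free monosaccharide minus one water), from
# textbook formulas and standard atomic weights. Chain mass =
# sum(increments) + H2O + aglycone phenol condensed (phenol - H2O).
# Independent of the package's per-atom bookkeeping.
residue_increments <- c(
  GlcA = 176.124, GlcA2S = 256.181, IdoA = 176.124, IdoA2S = 256.181,
  GlcN = 161.157, GlcNAc = 203.194, GlcNAc6S = 283.251,
  GlcNTFA = 257.164, GlcNS = 241.214, GlcNS6S = 321.271,
  GlcNS3S = 321.271, GlcNS3S6S = 401.328
)
aglycone_increments <- c("pNA-N3" = 230.271, pNP = 121.095, free = 0)
H2O_MASS <- 18.015

increment_mass <- function(oligo) {
  sum(residue_increments[oligo$tokens]) + H2O_MASS +
    aglycone_increments[[oligo$aglycone]]
}

# brute-force minimum-cost bijection by enumerating all permutations;
# the independent matching oracle (n small)
brute_force_cost <- function(cost) {
  n <- nrow(cost)
  perms <- hsoligo:::.permutations(n)
  min(apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)])))
}

all_fixture_oligos <- function() {
  setNames(lapply(fixture_names(), function(nm) get_fixture(nm)$oligo),
           fixture_names())
}
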