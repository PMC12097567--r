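# Recovery scenario: one comparison series tracks the reference's
# normalized shape closely (association 0.95) among seven weak trackers
# (association 0.25). The competitors' independent growth rates are kept
# well away from the reference's 5%/yr so that the association weight, not
# an accidental coincidence of growth rates, controls which factor wins.
planted_factor_spec <- function(seed) {
  synthetic_spec(
    n_factors = 8L,
    association = c(0.95, rep(0.25, 7)),
    factor_growth = c(0.15, -0.05, -0.02, 0.12, 0.15, 0.18, 0.21, 0.24),
    seed = seed)
}
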