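# National population of Mexico (millions) at census anchor years, used to
# build aggressor/susceptible scenario targets by piecewise-linear
# interpolation (linear extrapolation beyond 2020).
# Sources: 2010 census, 2015 intercensal survey, 2020 census (INEGI).
population_anchors:
  - {year: 2010, millions: 112.336538}
  - {year: 2015, millions: 119.938473}
  - {year: 2020, millions: 126.014024}
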