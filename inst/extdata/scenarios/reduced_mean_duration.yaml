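# Scenario 2: all band maximum mean durations scaled down by a common factor,
# penalty function and incidence ratios unchanged.
# NOTE: the published scenario's exact factor is not in the main text; 0.72 is
# a synthetic placeholder chosen to illustrate a duration reduction of the
# published scenario's rough magnitude. Edit to taste.
name: reduced mean duration
duration_scale: 0.72
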