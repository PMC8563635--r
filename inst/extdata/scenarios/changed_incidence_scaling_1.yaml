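# Scenario 3: adult incidence ratios reduced relative to the core set
# (1 / 0.50 / 0.30 / 0.25).
# NOTE: the published scenario's exact ratio values are not in the main text;
# this set is a synthetic placeholder that reduces adult incidence. Edit to
# taste.
name: changed incidence scaling 1
ratio_set: [1.0, 0.40, 0.20, 0.15]
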