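# Scenario 1: the child-mortality penalty is not applied anywhere; every
# country reaches the band maximum durations. Incidence is untouched.
name: ignoring penalty function
override_penalty: 0
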