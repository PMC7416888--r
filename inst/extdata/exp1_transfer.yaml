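# Transfer design: high-variance likelihood withheld until block 4.
experiment: exp1
run_length: 20
prior_only_period: 9
sd_mode: population
seed: 1
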