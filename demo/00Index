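full_sweep    Full-size hysteresis sweeps (N = 10000) at three triangle rates, with mean-field overlay
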