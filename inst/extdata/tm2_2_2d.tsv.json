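{"source":{"n_states":2,"n_symbols":2,"dimension":2,"step_cap":6,"mode":"exhaustive","sample_size":null,"seed":null},"total_halting":17688,"fallback":14.1104833098162,"fallback_margin":1,"dimension":2,"fallback_rule":"max covered K + fallback_margin"}
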