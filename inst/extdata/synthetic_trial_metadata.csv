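"fish_id","watershed","treatment","mass_g","fork_length_mm","chamber_volume_l","trace_path"
"SYN01","Siletz","Ambient",22.8,130.2,2,"synthetic_trial_trace.csv"
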