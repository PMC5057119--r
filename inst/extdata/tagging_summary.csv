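quantity,count
n_released,1177
n_recaptured_y1,207
n_recaptured_y2,38
n_kept_y1,199
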