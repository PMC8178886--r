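# Ed_J_mol=41400
temperature_K,kd_per_month
240.98,0.003
277.40,0.015
297.53,0.055
303.27,0.135
309.58,0.400
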