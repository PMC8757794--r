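{"brand_label":"Pipeline","phi_nom_mm":4,"L_nom_mm":20,"n_wires":48,"strut_len_mm":0.3023,"strut_width_mm":0.0428,"alpha_nom_deg":60}
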