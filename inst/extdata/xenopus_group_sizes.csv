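site,group,n_predators
CoGH,X_laevis,94
CoGH,X_gilli,111
Kleinmond,X_laevis,89
Kleinmond,X_gilli,105
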