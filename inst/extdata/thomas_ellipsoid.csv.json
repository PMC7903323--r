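{"shape":{"shape":"ellipsoid","a":1,"b":1,"c":3},"metadata":{"model":"thomas","rho_parent":0.215793559625326,"alpha":15,"kappa":0.1,"seed":44921576,"n_parents":11}}
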