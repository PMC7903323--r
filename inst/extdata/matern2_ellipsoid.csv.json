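{"shape":{"shape":"ellipsoid","a":1,"b":1,"c":3},"metadata":{"model":"matern2","rho":5,"R":0.3,"seed":43921573,"n_proposed":125}}
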