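{"shape":{"shape":"ellipsoid","a":1,"b":1,"c":3},"metadata":{"model":"csr","rho":5,"seed":42921570}}
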