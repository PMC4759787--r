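# Fitted rate constants, MCF7 cell line (h^-1), with the a priori
# molecular constants used by the observation layer.
k1: 0.02
k2: 1236.0
k3: 20.0
k4: 87.0
k5: 1765.0
k6: 565.0
Ymax: 300
Zmax: 1000
Zstar: 200
dsb_per_gy: 40
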