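kp1: 0.2
s: 0.4
Vb: 0.368
V0: 1.0
Pt0: 0.5
Pe_equil: 0.24
VPt0: 0.9
Ve: 10.0
bHOG: 0.5
aHOG: 0.5
kFps1: 0.5
keFps1: 6.0
nFps1: 2.0
kHOG: 0.2
keHOG: 6.0
nHOG: 2.0
c_osm: 2.0
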