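seed = 1
detection.scaleGrid =  4.00000000, 5.04000000, 6.35040000, 8.00150400,10.08189504,12.70318775,16.00000000
detection.wMin = 16
detection.wMax = 24
detection.k = 0.03
detection.angleSep = 30
detection.minArea = 100.5309649
tracking.dt = 1
tracking.q = 1
tracking.r = 1
tracking.p0 = 10
tracking.tauW = 5
tracking.tauA = 50
tracking.tauG = 0.15
tracking.gateRadius = NA
tracking.acIters = 100
tracking.acSmooth = 0.1
linking.T1 = 10
linking.T2 = 30
linking.D = 80
linking.minTrackLen = 5
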