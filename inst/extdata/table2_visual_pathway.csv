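# Reference values transcribed from the source study's Table II:
# phosphene-threshold medians (uA) and simulated current-density magnitudes
# (mA/m^2) in the lateral geniculate nucleus (LGN) and occipital cortex (OC)
# for both hemispheres, at 0.5 mA injected current.
montage,median_pt_uA,lgn_right,lgn_left,oc_right,oc_left
Fp2-So,75,16.9,18.8,10.2,10.1
F7-F8,100,24.0,18.7,10.9,8.2
So-rS,125,8.7,17.4,11.0,11.3
Cz-F8,125,35.5,16.0,19.7,19.6
Fp2-Cz,175,24.1,15.8,17.5,17.5
Fp2-rS,175,24.8,36.5,21.2,21.5
Fp2-O2,200,19.8,21.8,79.8,42.0
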