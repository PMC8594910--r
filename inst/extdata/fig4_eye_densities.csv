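# Eye-model right-eye current densities (mA/m^2) of the five unilateral
# eye-specific montages, as printed in the source study's regression-figure
# caption. Fp2-O2 is 95.4 here but 95.3 in the threshold table; both values
# are kept, flagged by the `caption_differs` column.
montage,eye_density_eye_model,caption_differs
Fp2-So,186.7,FALSE
So-rS,108,FALSE
Fp2-rS,103,FALSE
Fp2-Cz,89.4,FALSE
Fp2-O2,95.4,TRUE
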