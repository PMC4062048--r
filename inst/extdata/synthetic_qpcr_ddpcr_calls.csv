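assay,sample_id,ddpcr_cn,qpcr_cn
KIR2DL1,S01,2,2
KIR2DL1,S02,2,2
KIR2DL1,S03,2,2
KIR2DL1,S04,2,2
KIR2DL1,S05,2,2
KIR2DL1,S06,2,2
KIR2DL1,S07,2,2
KIR2DL1,S08,2,2
KIR2DL1,S09,2,2
KIR2DL1,S10,2,2
KIR2DL1,S11,2,2
KIR2DL1,S12,2,2
KIR2DL1,S13,2,2
KIR2DL1,S14,2,2
KIR2DL1,S15,1,1
KIR2DL1,S16,1,1
KIR2DL1,S17,1,1
KIR2DL1,S18,1,1
KIR2DL1,S19,3,3
KIR2DS1,S01,0,0
KIR2DS1,S02,0,0
KIR2DS1,S03,0,0
KIR2DS1,S04,0,0
KIR2DS1,S05,0,0
KIR2DS1,S06,0,0
KIR2DS1,S07,0,0
KIR2DS1,S08,1,1
KIR2DS1,S09,1,1
KIR2DS1,S10,1,1
KIR2DS1,S11,1,1
KIR2DS1,S12,1,1
KIR2DS1,S13,1,1
KIR2DS1,S14,1,1
KIR2DS1,S15,1,1
KIR2DS1,S16,1,1
KIR2DS1,S17,2,2
KIR2DS1,S18,2,2
KIR2DS1,S19,2,2
KIR2DS2,S01,1,1
KIR2DS2,S02,1,1
KIR2DS2,S03,1,1
KIR2DS2,S04,1,1
KIR2DS2,S05,1,1
KIR2DS2,S06,1,1
KIR2DS2,S07,1,1
KIR2DS2,S08,1,1
KIR2DS2,S09,1,1
KIR2DS2,S10,1,1
KIR2DS2,S11,2,2
KIR2DS2,S12,2,2
KIR2DS2,S13,2,2
KIR2DS2,S14,2,2
KIR2DS2,S15,2,2
KIR2DS2,S16,0,0
KIR2DS2,S17,0,0
KIR2DS2,S18,0,0
KIR2DS2,S19,0,0
KIR2DS3,S01,0,0
KIR2DS3,S02,0,0
KIR2DS3,S03,0,0
KIR2DS3,S04,0,0
KIR2DS3,S05,0,0
KIR2DS3,S06,0,0
KIR2DS3,S07,0,0
KIR2DS3,S08,0,0
KIR2DS3,S09,0,0
KIR2DS3,S10,1,1
KIR2DS3,S11,1,1
KIR2DS3,S12,1,1
KIR2DS3,S13,1,1
KIR2DS3,S14,1,1
KIR2DS3,S15,1,1
KIR2DS3,S16,1,1
KIR2DS3,S17,1,1
KIR2DS3,S18,2,2
KIR2DS3,S19,2,2
KIR2DS5,S01,0,0
KIR2DS5,S02,0,0
KIR2DS5,S03,0,0
KIR2DS5,S04,0,0
KIR2DS5,S05,0,0
KIR2DS5,S06,0,0
KIR2DS5,S07,1,1
KIR2DS5,S08,1,1
KIR2DS5,S09,1,1
KIR2DS5,S10,1,1
KIR2DS5,S11,1,1
KIR2DS5,S12,1,1
KIR2DS5,S13,1,1
KIR2DS5,S14,1,1
KIR2DS5,S15,1,1
KIR2DS5,S16,1,1
KIR2DS5,S17,2,2
KIR2DS5,S18,2,2
KIR2DS5,S19,2,2
KIR3DS1,S01,0,0
KIR3DS1,S02,0,0
KIR3DS1,S03,0,0
KIR3DS1,S04,0,0
KIR3DS1,S05,0,0
KIR3DS1,S06,0,0
KIR3DS1,S07,0,0
KIR3DS1,S08,0,0
KIR3DS1,S09,1,1
KIR3DS1,S10,1,1
KIR3DS1,S11,1,1
KIR3DS1,S12,1,1
KIR3DS1,S13,1,1
KIR3DS1,S14,1,1
KIR3DS1,S15,1,1
KIR3DS1,S16,1,1
KIR3DS1,S17,1,1
KIR3DS1,S18,2,2
KIR3DS1,S19,2,2
KIR3DL1,S01,0,0
KIR3DL1,S02,0,0
KIR3DL1,S03,0,0
KIR3DL1,S04,0,0
KIR3DL1,S05,0,0
KIR3DL1,S06,0,0
KIR3DL1,S07,0,0
KIR3DL1,S08,0,0
KIR3DL1,S09,0,0
KIR3DL1,S10,2,2
KIR3DL1,S11,2,2
KIR3DL1,S12,2,2
KIR3DL1,S13,2,2
KIR3DL1,S14,2,2
KIR3DL1,S15,2,2
KIR3DL1,S16,2,2
KIR3DL1,S17,2,2
KIR3DL1,S18,2,2
KIR3DL1,S19,0,1
KIR3DP1,S01,0,0
KIR3DP1,S02,0,0
KIR3DP1,S03,0,0
KIR3DP1,S04,0,0
KIR3DP1,S05,0,0
KIR3DP1,S06,0,0
KIR3DP1,S07,0,0
KIR3DP1,S08,0,0
KIR3DP1,S09,0,0
KIR3DP1,S10,1,1
KIR3DP1,S11,1,1
KIR3DP1,S12,1,1
KIR3DP1,S13,2,2
KIR3DP1,S14,2,2
KIR3DP1,S15,2,2
KIR3DP1,S16,2,2
KIR3DP1,S17,0,1
KIR3DP1,S18,0,1
KIR3DP1,S19,0,1
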