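well,sample_id,assay,channel_a_target,channel_b_target,digested,n_total,n_pp,n_pn,n_np,n_nn
A05,F-1268,KIR2DL5/RPP30,KIR2DL5,RPP30,FALSE,16000,1,54,405,15540
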