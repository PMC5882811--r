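cytokine_program	toy set	CCL5	CXCL9	CXCL10	IL16
ctl_markers	toy set	CD8A	GZMB	PRF1
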