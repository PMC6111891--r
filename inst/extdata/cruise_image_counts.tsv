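key	value
images_acquired_total	469967
images_removed_SO239	62948
images_removed_SO242-1	53058
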