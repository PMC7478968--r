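clone_id	status
grlB_B1	ok
grlB_B2	ok
grlB_B3	failed_sequencing
grlB_B4	ok
grlB_B5	failed_sequencing
grlB_B6	failed_sequencing
grlB_B7	failed_sequencing
grlB_B8	failed_sequencing
grlB_B9	ok
grlB_B10	ok
grlB_B11	failed_sequencing
grlB_B12	ok
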