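n_items,n_with_added,n_with_free
1483,521,585
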