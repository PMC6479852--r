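{"tp": 162, "fp": 9, "fn": 39, "printed_precision": "95%", "printed_recall": "80%"}
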