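{"command":"frobnicate","options":[],"package":"0.1.0","seed":null,"inputs":[],"outputs":[],"status":"failed"}
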