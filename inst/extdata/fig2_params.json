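{"tau":0.15479876160990713,"tau_r":0.18518518518518517,"D":8.0000000000000007e-05,"D_r":2.5899999999999999,"v_p":0.091999999999999998,"omega":0.69999999999999996}
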