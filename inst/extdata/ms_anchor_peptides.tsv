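sequence	observed_mz
SFIASEISSIER	1338.61
HQRTHTGEKPYVCR	1767.84
SDKPDLGYFFDDHVR	1810.76
LLFWGTPGVLIPPAEAAR	1908.01
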