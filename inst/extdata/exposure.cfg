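# chronic adult ingestion scenario for a liquid herbal preparation
ir = 0.008
ef = 365
ed = 70
bw = 70
# at omitted -> defaults to 365 * ed
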