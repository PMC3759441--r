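label	chain	start	end
SRS-1	A	96	117
SRS-2	A	198	210
SRS-3	A	233	240
SRS-4	A	288	304
SRS-5	A	359	369
SRS-6	A	470	478
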