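year,component,contribution_pct
2010,PC1,63.446
2010,PC2,22.217
2015,PC1,64.262
2015,PC2,20.183
2020,PC1,51.272
2020,PC2,24.486
2020,PC3,17.448
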