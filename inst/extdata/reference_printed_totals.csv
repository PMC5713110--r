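table,set,printed_total_pct
full,calibration,95.06
full,prediction,93.44
spa,calibration,92.59
spa,prediction,90.98
texture,calibration,71.60
texture,prediction,72.95
fusion,calibration,95.06
fusion,prediction,95.10
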