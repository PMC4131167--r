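2026-10-01 04:08:41 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
2026-10-01 04:08:47 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
2026-10-01 04:09:19 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
2026-10-01 04:17:07 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
2026-10-01 04:21:04 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
2026-10-01 04:24:35 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
2026-10-01 04:27:05 kddn frobnicate (seed 1, package 0.1.0, R 4.3.3) 
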