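# Synthetic TL-01-like narrowband-UVB lamp spectral power distribution.
# Constructed (not measured): asymmetric band peaking near 311 nm with
# minor mercury lines at 305.4 and 313.2 nm.
# Columns: wavelength_nm  relative_power (arbitrary units)
304.00 0.000000
304.25 0.000008
304.50 0.000133
304.75 0.001148
305.00 0.004933
305.25 0.010590
305.50 0.011352
305.75 0.006076
306.00 0.001624
306.25 0.000217
306.50 0.000015
306.75 0.000003
307.00 0.000009
307.25 0.000035
307.50 0.000127
307.75 0.000424
308.00 0.001293
308.25 0.003621
308.50 0.009296
308.75 0.021888
309.00 0.047269
309.25 0.093620
309.50 0.170056
309.75 0.283301
310.00 0.432847
310.25 0.606531
310.50 0.779475
310.75 0.918719
311.00 0.993103
311.25 0.990746
311.50 0.936023
311.75 0.839804
312.00 0.715558
312.25 0.579246
312.50 0.447524
312.75 0.337639
313.00 0.257011
313.25 0.187510
313.50 0.116797
313.75 0.062372
314.00 0.032098
314.25 0.016657
314.50 0.008426
314.75 0.004066
315.00 0.001864
315.25 0.000811
315.50 0.000335
315.75 0.000132
316.00 0.000049
316.25 0.000017
316.50 0.000006
316.75 0.000002
317.00 0.000001
317.25 0.000000
317.50 0.000000
317.75 0.000000
318.00 0.000000
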