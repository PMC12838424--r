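mz,mode,tol_da,kind,note
321.06,negative,0.03,nucleotide,dTMP chromatogram peak
330.07,negative,0.03,nucleotide,dAMP chromatogram peak
346.08,negative,0.03,nucleotide,dGMP chromatogram peak
438.094,negative,0.03,nucleotide,unknown double peak (modified dCMP candidate)
535.0360,negative,0.005,sugar-donor,UDP-xylose product peak
360.10,positive,0.03,nucleoside,precursor isolated for tandem MS (printed to 2 dp)
244.0901,positive,0.005,fragment,tandem-MS fragment of the 360.10 precursor
128.0450,positive,0.005,fragment,tandem-MS fragment of the 360.10 precursor
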