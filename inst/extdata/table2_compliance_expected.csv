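element,brown,orange,black
Al,not_applicable,not_applicable,not_applicable
V,not_applicable,not_applicable,not_applicable
Cr,exceeds,exceeds,exceeds
Fe,not_applicable,not_applicable,not_applicable
Co,exceeds,exceeds,within
Ni,exceeds,exceeds,within
Cu,exceeds,below_loq,within
Cd,within,within,within
Ba,within,within,within
Hg,within,within,within
Pb,exceeds,exceeds,within
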