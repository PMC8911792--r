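analyte,class,mean,sd,unit
Gallic acid,polyphenol,104.84,9.21,µg/100 g DW
m-Hydroxybenzoic acid,polyphenol,0.54,0.07,µg/100 g DW
Protocatechuic acid,polyphenol,17.20,0.65,µg/100 g DW
p-Hydroxybenzoic acid,polyphenol,18.28,0.32,µg/100 g DW
Syringic acid,polyphenol,10.22,0.17,µg/100 g DW
Ferulic acid,polyphenol,44.09,1.06,µg/100 g DW
Sinapic acid,polyphenol,0.43,0.09,µg/100 g DW
Catechin,polyphenol,72.04,1.16,µg/100 g DW
Quercetin,polyphenol,10.22,0.35,µg/100 g DW
Hyperoside,polyphenol,19.89,0.50,µg/100 g DW
Procyanidin B1,polyphenol,71.51,0.97,µg/100 g DW
Procyanidin B2,polyphenol,824.73,13.26,µg/100 g DW
Ferulic acid methyl ester,polyphenol,39.78,1.04,µg/100 g DW
Cyanidol-3-glucoside,anthocyanin,43.65,1.87,µg/100 g DW
Petunidol-3-glucoside,anthocyanin,79.54,1.65,µg/100 g DW
Dolphinidol-3-glucoside,anthocyanin,51.41,1.23,µg/100 g DW
Peonidol-3-glucoside,anthocyanin,83.42,2.02,µg/100 g DW
Malvidol-3-glucoside,anthocyanin,519.92,14.65,µg/100 g DW
Peonidol-3-acetylglucoside,anthocyanin,15.52,0.48,µg/100 g DW
Malvidol-3-acetylglucoside,anthocyanin,119.31,9.04,µg/100 g DW
Peonidol-3-coumarylglucoside,anthocyanin,7.76,0.83,µg/100 g DW
Malvidol-3-coumarylglucoside,anthocyanin,49.47,0.79,µg/100 g DW
Malic acid,organic acid,373,7,mg/100 g DW
Citric acid,organic acid,415,5,mg/100 g DW
Ascorbic acid,organic acid,36,1,mg/100 g DW
Acetic acid,organic acid,500,3,mg/100 g DW
Tartaric acid,organic acid,4279,81,mg/100 g DW
DPPH,antioxidant,15.09,1.72,mmol TE/100 g DW
ABTS,antioxidant,18.67,0.89,mmol TE/100 g DW
L*,chromatic,60.10,0.15,
a*,chromatic,9.72,0.09,
b*,chromatic,1.22,0.05,
C*,chromatic,9.80,0.07,
H*,chromatic,7.2,0.1,deg
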