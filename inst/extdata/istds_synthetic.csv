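"name","target_mz","rt","conc"
"D3-propionylglycine",133.0698,2.33,25
"13C5-oxoglutaric acid",150.031,1.19,25
"13C4-3-hydroxybutyric acid",107.0535,2.56,25
"D4-adipic acid",149.0757,4.93,25
"D2-glycolic acid",77.0213,0.78,25
"D4-glutaric acid",135.0601,4.11,25
"D4-citric acid",195.0448,1.88,25
"D5-ethylmalonic acid",136.0664,4.58,25
"D3-glyceric acid",108.0382,0.76,25
"D3-malic acid",136.0331,1.04,25
"D3-hexanoylglycine",175.1167,6.86,25
"D4-sebacic acid",205.1383,9.05,25
"D3-methylmalonic acid",120.0382,2.89,25
"13C3-lactic acid",92.0345,1.18,25
"D3-3-hydroxy-3-methyl-glutaric acid",164.0644,3.68,25
"D3-methyl citric acid",208.0542,3.92,25
"D5-pyroglutamic acid",133.0667,1.84,25
"13C3-pyruvic acid",90.0188,0.91,25
"13C5-succinylacetone",162.0674,4.5,25
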