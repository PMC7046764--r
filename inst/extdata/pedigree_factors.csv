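# Pedigree-matrix indicator-score -> lognormal uncertainty factor lookup.
# Factors follow the published ecoinvent-style basic uncertainty scheme;
# two cells never published (geographical score 4, technological score 2)
# are interpolated monotonically between their neighbours.
indicator,score,factor
reliability,1,1.00
reliability,2,1.05
reliability,3,1.10
reliability,4,1.20
reliability,5,1.50
completeness,1,1.00
completeness,2,1.02
completeness,3,1.05
completeness,4,1.10
completeness,5,1.20
temporal,1,1.00
temporal,2,1.03
temporal,3,1.10
temporal,4,1.20
temporal,5,1.50
geographical,1,1.00
geographical,2,1.01
geographical,3,1.02
geographical,4,1.05
geographical,5,1.10
technological,1,1.00
technological,2,1.10
technological,3,1.20
technological,4,1.50
technological,5,2.00
sample_size,1,1.00
sample_size,2,1.02
sample_size,3,1.05
sample_size,4,1.10
sample_size,5,1.20
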