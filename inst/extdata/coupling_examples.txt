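# Two raw Hiyama coupling reactions (aryl halide + aryl silane, biaryl
# product, KF activation). The fluoride in the first entry is written as
# the [F-] anion; sources sometimes print a bare [F], which this package
# normalizes to fluoride.
CC(=O)c1ccc(I)cc1.F[Si](c1ccccc1)(c1ccccc1)c1ccccc1.[F-].[K+]>>CC(=O)c1ccc(c2ccccc2)cc1
CC[Si](Cl)(Cl)c1ccc(C)cc1.N#Cc1ccc(Br)cc1.[F-].[K+]>>Cc1ccc(-c2ccc(C#N)cc2)cc1
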