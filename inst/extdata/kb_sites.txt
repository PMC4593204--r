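# Documented 10-bp NFkB binding sites used to build the packaged kB weight
# matrix (pseudocount 0.5 per base per column, uniform background).
# site	source_gene
GGGACTTTCC	IGK_enhancer
GGGACTTTCC	HIV1_LTR
GGGAATCTCC	IL2RA
GGGAAATTCC	IFNB1
GGGATTTTCC	IL6
GGGAAATCCC	TNFAIP3
GGGAAAGTCC	CXCL10
GGGGATTCCC	HLA_classI
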