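sbml_id	canonical_name	class	chain
X0	BoundaryAcylCoA	acyl-CoA	4
S1	Intermediate	other	NA
Xn	ProductPool	other	NA
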