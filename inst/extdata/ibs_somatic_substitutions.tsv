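# Substitution counts among inferred identity-by-state somatic SNVs shared
# by the two tumor samples of a familial colorectal-cancer exome cohort.
# Rows: reference allele; columns: alternate allele; diagonal undefined.
ref	A	C	T	G
A	NA	38	20	149
C	43	NA	158	63
T	32	169	NA	38
G	220	63	47	NA
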