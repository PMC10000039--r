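# Genotype matrix of sites with a fixed SNP pattern in the high-milk-yield
# group (Sahiwal, Gir) and a variable pattern in the low-milk-yield group
# (reference result set, transcribed as printed; the LPIN1 85211528 column
# contains a C/T call outside its declared Ref/Alt pair).
field	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14
gene	GHR	GHR	TLR4	TLR4	LPIN1	LPIN1	LPIN1	CACNA1C	ZBTB16	ITGA1	ANK1	ANK1	NT5E	NT5E
location	31685773	31685984	107083326	107083914	85187074	85209309	85211528	11271411	59717709	25983121	36054194	36076037	64035090	64065719
ref	C	A	A	C	G	C	C	C	C	C	G	G	C	G
alt	G	G	C	A	A	T	G	T	T	T	A	A	T	A
protein	392(G/A)	462(N/D)	151(A/T)	347(N/G)	772(R/K)	631(A/E)	542(R/P)	204(E/K)	393(V/M)	588(V/M)	111(P/S)	127(R/H)	475(C/F)	151(A/V)
Sahiwal 1	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Sahiwal 2	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Sahiwal 3	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Sahiwal 4	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Gir 1	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Gir 2	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Gir 3	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Gir 4	C/C	A/A	A/A	C/C	G/G	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Amritmahal	C/C	A/A	A/A	C/C	G/A	C/C	C/C	C/C	C/C	C/C	G/G	G/G	C/C	G/G
Dangi	C/G	A/G	A/C	C/A	G/G	C/C	C/G	C/C	C/T	C/C	G/G	G/G	C/C	G/G
Gaolao	C/G	A/A	A/C	C/C	G/G	C/T	C/C	C/C	C/C	C/C	G/G	G/G	T/T	G/G
Deoni	C/C	A/A	A/C	C/C	G/G	C/C	C/G	C/T	C/T	C/C	G/G	G/G	C/C	G/A
Pulikulam	C/G	A/A	A/A	C/C	G/A	C/C	C/T	C/C	C/C	C/T	G/A	G/G	C/C	G/G
Hallikar	C/C	A/A	A/A	C/C	G/A	C/C	C/G	C/C	C/C	C/C	G/G	G/A	C/C	G/G
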