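# Genotype matrix of sites with a fixed SNP pattern in the low-milk-yield
# group and a variable pattern in the high-milk-yield group (reference
# result set, transcribed as printed; note the ZBTB16 59718206 column has a
# Hallikar A/A call inside the nominally fixed low-yield group, and the
# FGF2 column has three missing ('-') high-yield calls).
field	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10
gene	MFGE8	FGF2	TLR4	LPIN1	NUP98	PTK2	ZBTB16	ZBTB16	DDIT3	NT5E
location	20518217	37920746	107080326	85205642	32707374	2973942	59717979	59718206	64346576	64102580
ref	A	G	G	T	G	A	T	G	C	G
alt	T	A	A	G	A	C	C	A	T	T
protein	328(S/R)	19(G/R)	67(R/K)	766(S/P)	548(H/Y)	904(D/A)	598(G/R)	627(A/V)	87(S/L)	8(T/N)
Sahiwal 1	A/A	G/G	G/A	T/T	G/G	A/A	T/T	G/G	C/T	G/G
Sahiwal 2	A/A	G/G	G/G	T/G	G/G	A/A	T/T	G/G	C/C	G/T
Sahiwal 3	A/A	G/A	G/G	T/T	G/A	A/A	T/T	G/A	C/C	G/G
Sahiwal 4	A/A	-	G/G	T/T	G/A	A/A	T/T	G/G	C/C	G/G
Gir 1	A/T	-	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Gir 2	A/A	-	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Gir 3	A/A	G/G	G/G	T/T	G/G	A/C	T/C	G/G	C/C	G/G
Gir 4	A/A	G/G	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Amritmahal	A/A	G/G	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Dangi	A/A	G/G	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Gaolao	A/A	G/G	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Deoni	A/A	G/G	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Pulikulam	A/A	G/G	G/G	T/T	G/G	A/A	T/T	G/G	C/C	G/G
Hallikar	A/A	G/G	G/G	T/T	G/G	A/A	T/T	A/A	C/C	G/G
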