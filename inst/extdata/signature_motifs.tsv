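name	pattern	family	mandatory	near_match	fallback
ploop	(I/V/L)GxGx(S/F/G)GxV	MPK	FALSE	0	
atp_anchor	VA(I/V/M)KK(I/M)xxx(F/Y)	MPK	FALSE	0	
cloop	HRD(L/I)KPxN	MPK	TRUE	0	D(L/I/V)K
dfg	DFGLAR	MPK	FALSE	0	
tloop	T(D/E)Y	MPK	TRUE	0	
ape	TRWYRAPE	MPK	FALSE	0	
cloop	D(L/I/V)K	MKK	TRUE	0	
activation	GTxxYMSPER	MKK	TRUE	1	
spacing	(S/T)xxxxx(S/T)	MKK	FALSE	0	
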