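node	sign	species	rc
Casp6	-	Casp6	11
Casp6	+	Casp9	12
CDK1	+	Wee1	13
CDK1	-	CDK1	14
Wee1	-	Wee1	13
JNK	-	JNK	15
JNK	+	EGFR	17
BID	-	BID	16
BID	-	BID	25
EGFR	-	EGFR	17
EGFR	-	EGFR	32
PUMA	-	PUMA	19
PUMA	+	p53	27
Casp3	-	Casp3	1
Casp3	+	XIAP	2
Casp3	+	SMAC	4
Casp3	+	Casp8	7
Casp3	-	Casp3	8
Casp3	+	Casp9	9
Casp3	+	Casp6	11
Casp3	+	MOMP	30
Casp9	-	Casp9	9
Casp9	-	Casp9	12
Casp9	+	PUMA	19
Casp9	-	Casp9	24
Casp9	+	BCL2	26
HER2	-	HER2	20
HER2	-	HER2	31
Casp8	-	Casp8	3
Casp8	+	RIP1	6
Casp8	-	Casp8	7
Casp8	+	Casp3	8
Casp8	+	BID	25
Casp8	+	EGFR	32
Apop	+	Casp3	1
XIAP	-	XIAP	2
XIAP	+	SMAC	21
XIAP	+	Casp9	24
XIAP	+	HER2	31
SMAC	+	Casp8	3
SMAC	-	SMAC	4
SMAC	+	BCL2	5
SMAC	-	SMAC	21
SMAC	+	MOMP	29
BCL2	-	BCL2	5
BCL2	+	p53	10
BCL2	+	CDK1	14
BCL2	+	JNK	15
BCL2	+	BID	16
BCL2	+	STAT3	22
BCL2	-	BCL2	26
RIP1	-	RIP1	6
RIP1	+	TNFR	23
p53	-	p53	10
p53	+	AKT	18
p53	-	p53	27
AKT	-	AKT	18
AKT	+	HER2	20
STAT3	-	STAT3	22
TNFR	-	TNFR	23
DAPK1	-	DAPK1	28
MOMP	+	DAPK1	28
MOMP	-	MOMP	29
MOMP	-	MOMP	30
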