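synonym	token
atp6	atp6
atp8	atp8
cob	cob
cox1	cox1
cox2	cox2
cox3	cox3
nad1	nad1
nad2	nad2
nad3	nad3
nad4	nad4
nad4L	nad4L
nad5	nad5
nad6	nad6
trnA	trnA
trnC	trnC
trnD	trnD
trnE	trnE
trnF	trnF
trnG	trnG
trnH	trnH
trnI	trnI
trnK	trnK
trnL1	trnL1
trnL2	trnL2
trnM	trnM
trnN	trnN
trnP	trnP
trnQ	trnQ
trnR	trnR
trnS1	trnS1
trnS2	trnS2
trnT	trnT
trnV	trnV
trnW	trnW
trnY	trnY
rrnS	rrnS
rrnL	rrnL
COI	cox1
CO1	cox1
COXI	cox1
COX1	cox1
cytochrome c oxidase subunit 1	cox1
cytochrome c oxidase subunit I	cox1
COII	cox2
CO2	cox2
COXII	cox2
COX2	cox2
cytochrome c oxidase subunit 2	cox2
cytochrome c oxidase subunit II	cox2
COIII	cox3
CO3	cox3
COXIII	cox3
COX3	cox3
cytochrome c oxidase subunit 3	cox3
cytochrome c oxidase subunit III	cox3
CYTB	cob
COB	cob
cytochrome b	cob
ATP6	atp6
ATPase6	atp6
ATP synthase F0 subunit 6	atp6
ATP8	atp8
ATPase8	atp8
ATP synthase F0 subunit 8	atp8
ND1	nad1
NADH1	nad1
NADH dehydrogenase subunit 1	nad1
ND2	nad2
NADH2	nad2
NADH dehydrogenase subunit 2	nad2
ND3	nad3
NADH3	nad3
NADH dehydrogenase subunit 3	nad3
ND4	nad4
NADH4	nad4
NADH dehydrogenase subunit 4	nad4
ND5	nad5
NADH5	nad5
NADH dehydrogenase subunit 5	nad5
ND6	nad6
NADH6	nad6
NADH dehydrogenase subunit 6	nad6
ND4L	nad4L
NADH dehydrogenase subunit 4L	nad4L
12S	rrnS
12S rRNA	rrnS
srRNA	rrnS
s-rRNA	rrnS
small subunit ribosomal RNA	rrnS
12S ribosomal RNA	rrnS
rns	rrnS
16S	rrnL
16S rRNA	rrnL
lrRNA	rrnL
l-rRNA	rrnL
large subunit ribosomal RNA	rrnL
16S ribosomal RNA	rrnL
rnl	rrnL
tRNA-Ala	trnA
trnA(a)	trnA
tRNA-Cys	trnC
trnC(c)	trnC
tRNA-Asp	trnD
trnD(d)	trnD
tRNA-Glu	trnE
trnE(e)	trnE
tRNA-Phe	trnF
trnF(f)	trnF
tRNA-Gly	trnG
trnG(g)	trnG
tRNA-His	trnH
trnH(h)	trnH
tRNA-Ile	trnI
trnI(i)	trnI
tRNA-Lys	trnK
trnK(k)	trnK
tRNA-Met	trnM
trnM(m)	trnM
tRNA-Asn	trnN
trnN(n)	trnN
tRNA-Pro	trnP
trnP(p)	trnP
tRNA-Gln	trnQ
trnQ(q)	trnQ
tRNA-Arg	trnR
trnR(r)	trnR
tRNA-Thr	trnT
trnT(t)	trnT
tRNA-Val	trnV
trnV(v)	trnV
tRNA-Trp	trnW
trnW(w)	trnW
tRNA-Tyr	trnY
trnY(y)	trnY
tRNA-Leu (UUR)	trnL2
tRNA-Leu(UUR)	trnL2
trnL2(taa)	trnL2
tRNA-Leu2	trnL2
trnL-uur	trnL2
tRNA-Leu (CUN)	trnL1
tRNA-Leu(CUN)	trnL1
trnL1(tag)	trnL1
tRNA-Leu1	trnL1
trnL-cun	trnL1
tRNA-Ser (AGN)	trnS1
tRNA-Ser(AGN)	trnS1
trnS1(tct)	trnS1
tRNA-Ser1	trnS1
trnS-agn	trnS1
tRNA-Ser (UCN)	trnS2
tRNA-Ser(UCN)	trnS2
trnS2(tga)	trnS2
tRNA-Ser2	trnS2
trnS-ucn	trnS2
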