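# Synthetic ring-system reference table (stand-in for a corpus-derived census).
# Columns: ring_key<TAB>count
C1CC1	1000
C1CCC1	1000
C1CCCC1	1000
C1CCCCC1	1000
C1CCNC1	1000
C1CCNCC1	1000
C1CCNNC1	1000
C1CCOC1	1000
C1CCOCC1	1000
C1CCONC1	1000
C1CCOOC1	1000
C1CN1	1000
C1CNC1	1000
C1CNCCN1	1000
C1CNCN1	1000
C1CNCNC1	1000
C1CNCOC1	1000
C1CNN1	1000
C1CNNC1	1000
C1CNNCN1	1000
C1CNNN1	1000
C1CNNNC1	1000
C1CNNNN1	1000
C1CNNOC1	1000
C1CNOC1	1000
C1CNOCN1	1000
C1CNON1	1000
C1CNONC1	1000
C1CNONN1	1000
C1CNOOC1	1000
C1CNOON1	1000
C1CO1	1000
C1COC1	1000
C1COCCN1	1000
C1COCCO1	1000
C1COCN1	1000
C1COCNN1	1000
C1COCO1	1000
C1COCOC1	1000
C1COCON1	1000
C1CON1	1000
C1CONCN1	1000
C1CONCO1	1000
C1CONN1	1000
C1CONNN1	1000
C1CONNO1	1000
C1CONO1	1000
C1CONOC1	1000
C1CONON1	1000
C1COO1	1000
C1COOC1	1000
C1COOCN1	1000
C1COOCO1	1000
C1COON1	1000
C1COONN1	1000
C1COONO1	1000
C1COOO1	1000
C1COOOC1	1000
C1COOON1	1000
C1COOOO1	1000
C1NCN1	1000
C1NCNCN1	1000
C1NCNN1	1000
C1NCNNN1	1000
C1NCNON1	1000
C1NCO1	1000
C1NCOCN1	1000
C1NCOCO1	1000
C1NCON1	1000
C1NCONN1	1000
C1NCONO1	1000
C1NCOO1	1000
C1NCOON1	1000
C1NCOOO1	1000
C1NN1	1000
C1NNCNN1	1000
C1NNCO1	1000
C1NNCON1	1000
C1NNCOO1	1000
C1NNN1	1000
C1NNNCO1	1000
C1NNNN1	1000
C1NNNNN1	1000
C1NNNNO1	1000
C1NNNO1	1000
C1NNNON1	1000
C1NNNOO1	1000
C1NNO1	1000
C1NNOCO1	1000
C1NNON1	1000
C1NNONN1	1000
C1NNONO1	1000
C1NNOO1	1000
C1NNOON1	1000
C1NNOOO1	1000
C1NO1	1000
C1NOCNO1	1000
C1NOCO1	1000
C1NOCON1	1000
C1NOCOO1	1000
C1NON1	1000
C1NONCO1	1000
C1NONNO1	1000
C1NONO1	1000
C1NONON1	1000
C1NONOO1	1000
C1NOO1	1000
C1NOOCO1	1000
C1NOON1	1000
C1NOONO1	1000
C1NOOO1	1000
C1NOOON1	1000
C1NOOOO1	1000
C1OCO1	1000
C1OCOCO1	1000
C1OCONO1	1000
C1OCOO1	1000
C1OCOOO1	1000
C1ONNNO1	1000
C1ONNO1	1000
C1ONNOO1	1000
C1ONO1	1000
C1ONONO1	1000
C1ONOO1	1000
C1ONOOO1	1000
C1OO1	1000
C1OOCOO1	1000
C1OONOO1	1000
C1OOO1	1000
C1OOOO1	1000
C1OOOOO1	1000
N1NNN1	1000
N1NNNNN1	1000
N1NNONN1	1000
N1NNOON1	1000
N1NON1	1000
N1NONNO1	1000
N1NONON1	1000
N1NOO1	1000
N1NOONO1	1000
N1NOOON1	1000
N1NOOOO1	1000
N1ONO1	1000
N1ONONO1	1000
N1ONOOO1	1000
N1OONOO1	1000
N1OOO1	1000
N1OOOOO1	1000
O1OOO1	1000
O1OOOOO1	1000
[nH]1[nH][nH]1	1000
[nH]1[nH][nH][nH][nH]1	1000
[nH]1[nH][nH]o[nH]1	1000
[nH]1[nH]o1	1000
[nH]1[nH]o[nH]o1	1000
[nH]1[nH]oo[nH]1	1000
[nH]1[nH]ooo1	1000
[nH]1o[nH]oo1	1000
[nH]1oo1	1000
[nH]1oooo1	1000
c1ccc2ccccc2c1	1000
c1ccccc1	100000
c1ccncc1	1000
o1oo1	1000
o1oooo1	1000
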