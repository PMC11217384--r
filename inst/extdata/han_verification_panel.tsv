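gene	vid	consequence	hgvs
APBA3	19:3751091:T/C	missense	NM_004886.3:c.1661A>G(p.His554Arg)
ARHGAP39	8:145755853:C/T	missense	NM_025251.1:c.3298G>A(p.Val1100Met)
ARHGEF11	1:156906736:G/C	missense	NM_014784.3:c.4382C>G(p.Thr1461Ser)
BAI2	1:32222059:G/A	missense	NM_001703.2:c.379C>T(p.Arg127Trp)
C14orf177	14:99183438:T/C	missense	NM_182560.2:c.205T>C(p.Cys69Arg)
CDH10	5:24487935:G/C	missense	NM_006727.3:c.2204C>G(p.Thr735Ser)
CLTCL1	22:19175545:TTG/-	inframe_indel	NM_007098.3:c.4380_4382delCAA(p.Asn1460del)
CPLX4	18:56985594:G/A	missense	NM_181654.3:c.101C>T(p.Pro34Leu)
DNAH5	5:13759047:C/G	missense	NM_001369.2:c.10327G>C(p.Asp3443His)
DPPA4	3:109047930:T/C	missense	NM_018189.3:c.685A>G(p.Arg229Gly)
ERC1	12:1291147:A/T	missense	NM_178039.2:c.1848A>T(p.Gln616His)
FUBP1	1:78430904:C/A	missense	NM_003902.3:c.485G>T(p.Arg162Leu)
GEMIN7,ZNF296	19:45579582:G/A	missense	NM_145288.1:c.50C>T(p.Pro17Leu)
IL21R-AS1,IL21R	16:27460434:G/A	missense	NM_181079.4:c.1513G>A(p.Ala505Thr)
IL6R	1:154437680:G/A	missense	NM_000565.3:c.1231G>A(p.Gly411Arg)
KCNAB1	3:155861100:C/T	missense	NM_003471.3:c.133C>T(p.Pro45Ser)
KIF17	1:21009232:C/T	missense	NM_020816.2:c.2377G>A(p.Gly793Arg)
KNDC1	10:135009249:G/A	missense	NM_152643.6:c.1658G>A(p.Arg553His)
MAP2	2:210574665:A/G	missense	NM_002374.3:c.4760A>G(p.Lys1587Arg)
NPTX2	7:98256538:C/T	missense	NM_002523.2:c.950C>T(p.Thr317Met)
PGAM2	7:44104852:C/T	missense	NM_000290.3:c.277G>A(p.Gly93Arg)
PLA2G4B,JMJD7-PLA2G4B	15:42138538:C/G	missense	NM_005090.3:c.2431C>G(p.His811Asp)
PTCH1	9:98209454:G/A	missense	NM_000264.3:c.4084C>T(p.Pro1362Ser)
SCN11A	3:38921541:G/A	missense	NM_014139.2:c.3293C>T(p.Thr1098Ile)
SH3TC2	5:148392170:C/T	missense	NM_024577.3:c.3181G>A(p.Glu1061Lys)
SHANK1	19:51172180:G/A	missense	NM_016148.2:c.3037C>T(p.Pro1013Ser)
SLC39A6	18:33702217:T/C	missense	NM_012319.3:c.1157A>G(p.His386Arg)
SORL1	11:121420769:G/A	missense	NM_003105.5:c.2152G>A(p.Val718Met)
SSH1	12:109182656:T/A	missense	NM_018984.3:c.2258A>T(p.Lys753Met)
SYNJ1	21:34053882:C/A	missense	NM_203446.2:c.1394G>T(p.Arg465Leu)
SYT8	11:1857115:G/C	splice	NM_138567.3:c.301-1G>C(.)
TAOK2	16:29998819:C/T	missense	NM_001252043.1:c.2887C>T(p.Arg963Trp)
TENM1	X:123695656:C/T	missense	NM_014253.3:c.2299G>A(p.Gly767Arg)
TMEM132A	11:60696363:G/A	missense	NM_017870.3:c.797G>A(p.Arg266Gln)
TSEN34	19:54696153:G/A	missense	NM_024075.3:c.674G>A(p.Arg225Lys)
TUFM	16:28856781:C/T	missense	NM_003321.4:c.268G>A(p.Ala90Thr)
YLPM1	14:75276681:C/T	missense	NM_019589.2:c.5008C>T(p.Pro1670Ser)
TRIO	5:14488193:T/C	missense	NM_007118.2:c.7456T>C(p.Trp2486Arg)
RAB41	X:69502652:G/C	missense	NM_001032726.2:c.181G>C(p.Ala61Pro)
GPRASP2	X:101970390:C/T	missense	NM_138437.5:c.593C>T(p.Pro198Leu)
INADL	1:62240913:TAA/-	inframe_indel	NM_176877.2:c.757_759delAAT(p.Asn253del)
FOXP1	3:71102805:C/A	missense	NM_032682.5:c.402G>T(p.Gln134His)
NLRC5	16:57060387:C/T	missense	NM_032206.4:c.1532C>T(p.Ala511Val)
LPCAT2	16:55575825:C/T	stop_gain	XM_005256006.1:c.928C>T(p.Arg310Ter)
ABCA10	17:67211999:A/G	missense	NM_080282.3:c.815T>C(p.Leu272Ser)
SUCLG2	3:67459404:G/C	missense	XM_005264773.1:c.1117C>G(p.His373Asp)
PIK3C2A	11:17113578:C/T	missense	NM_002645.2:c.4607G>A(p.Arg1536His)
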