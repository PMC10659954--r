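# Synthetic stand-in table of mean amino-acid residue volumes (nm^3).
# Values are the widely tabulated mean volumes of buried residues in folded
# proteins (tessellation-based statistics), rounded to 4 digits; PTM-residue
# and cap volumes are constructed from the parent residue plus standard
# group-volume increments. This table is a constructed stand-in, not a
# transcription of any single published tessellation study.
residue,volume_nm3
GLY,0.0638
ALA,0.0893
SER,0.0935
CYS,0.1025
THR,0.1196
PRO,0.1213
VAL,0.1382
ASP,0.1144
ASN,0.1223
ILE,0.1630
LEU,0.1631
MET,0.1658
GLU,0.1388
GLN,0.1469
HIS,0.1575
LYS,0.1651
ARG,0.1903
PHE,0.1908
TYR,0.1946
TRP,0.2264
ACE,0.0540
NME,0.0450
SNC,0.1330
CSS,0.1290
SMC,0.1290
XCN,0.1300
CSO,0.1180
CSD,0.1330
OCS,0.1480
QCS,0.1450
CGL,0.3480
IYY,0.2050
SEP,0.1610
TPO,0.1870
PTR,0.2620
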