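# toy receptor annotation: a small list of signaling-receptor gene symbols
# (uppercased on ingest); supply a full ligand-receptor catalogue for real use
NEO1
PTCH1
CADM4
ZNRF3
OSMR
UNC5B
SEMA3F
NOTCH2
EGFR
FGFR1
MET
AXL
ROBO1
DCC
UNC5A
PLXNB1
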