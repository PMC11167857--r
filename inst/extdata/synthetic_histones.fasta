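>H1x1 synthetic stand-in for a tilapia histone H1 isoform X1; N-terminus carries the K16 site
SEEAPAPAPAPAKAAKKKTTASKPKKVGPSVGEAAKPKAAAKPKVAKKAAAKKPAGARRK
ASGPPVSELITKAVAASKERSGVSLAALKKALAAAGYDVEKNNSRIKLGLKSLVSKGTLV
QTKGTGASGSFKLNKKAASGEAKPKA
>H1like synthetic stand-in for a tilapia histone H1-like protein; serine 1 is the acetylation site
SEEAPAPAPAPAKAAKKKKTTASKPKKVGPSVGEAAKPKAAAKPKVAKKAAAKKPAGARR
KASGPPVSELITKAVAASKERSGVSLAALKKALAAAGYDVEKNNSRIKLGLKSLVSKGTL
VQTKGTGASGSFKLNKKAASGEAKPKA
>H3 synthetic stand-in for tilapia histone H3; canonical N-tail with K14 and K18 sites
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
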