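>human_H1 synthetic stand-in for human histone H1; shares S1, carries R at position 24 where the tilapia H1 K16 aligns
SETAPAAPAEEAPAPAPAPAKAARKKTTASKPKKVGPSVGEAAKPKAAAKPKVAKKAAAK
KPAGARRKASGPPVSELITKAVAASKERSGVSLAALKKALAAAGYDVEKNNSRIKLGLKS
LVSKGTLVQTKGTGASGSFKLNKKAASGEAKPKA
>human_H3 synthetic stand-in for human histone H3; N-tail identical to the tilapia stand-in
ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTEL
LIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIM
PKDIQLARRIRGERA
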