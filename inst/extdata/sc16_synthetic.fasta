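>SC16_synthetic synthetic stand-in: printed SC16 cysteine positions and anchor residues, random elsewhere; numbering offset 18
TGAMFWVSGFGRWSECFGQGVKCCMNSKDFWQGFKWEVWHHDLDHMKGAVIFQLLPLNCT
GLGDWVWGRKKCFIQWQCCVPLYTKHAVRGLCNPMAYVL
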