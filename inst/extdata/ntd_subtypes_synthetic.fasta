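>H1.0 human H1.0 linker-histone NTD, residues 1-26
MTENSTSAPAAKPKRAKASKKSTDHP
>H1.1 human H1.1 linker-histone NTD, synthetic reconstruction consistent with the published basic-subregion composition (21 residues, 9 Arg/Lys, 3 Pro/Gly)
MSETVPPAPAASAAPEKPLAKKAKPKKAAAPAAKAKK
>H1.2 human H1.2 linker-histone NTD, synthetic reconstruction consistent with the published basic-subregion composition (18 residues, 8 Arg/Lys, 4 Pro/Gly)
MSETAPAAPAAPAPAEKTPVKKKAAKKAGGAGRKAS
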