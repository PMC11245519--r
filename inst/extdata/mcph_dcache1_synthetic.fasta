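>McpH_dCache1 synthetic stand-in for the McpH ligand-binding domain (full-length numbering; binding-site residues at published positions)
VERYGFMDDLGATEPITWEPMGDAVELEFEIRIGQDNATSNDNKKNLITTIFSGLAVKDS
YVIEDVIPLFEQEEIFFSPHSTSEPGTAGAGLDFPNISNRDEVWDGAIYRCTESALTASD
YIIAPIIGRRRLLDMRKKCWFRGVTSAPAFRKENIDKLGGVFSPFSFEDEDQQSEFDPRY
VGFIGGPTMKTSAYVRAQVNVGKVGKKAVTHAPMNVDHHEVAEIYIVLSQEAEDSTTKSS
VRYASGSAIMPMIRIAGIEMKVVNTALPRALAEAVGVGIP
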