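((EXT,(((CYT,NUC)nuccyt,(MIT,(CHL,PLAS)plastid)endosym)soluble,(PER,(ER,(GOL,VAC)golvac)secretory)organelle)intracell)nonmem,(PM,(((MITM,CHLM)endosymm,(NUCM,ERM)nucerm)organellarm,(PERM,(GOLM,VACM)golvacm)secretorym)intramem)mem)root;
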