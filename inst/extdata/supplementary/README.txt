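Place the published DNAJB6 structural-model PDB files here to enable the
corresponding distance and flexibility checks:

  DNAJB6 monomer model_Robetta_5.pdb
  DNAJB6 dimer model_Haddock.pdb

These files are distributed as journal supplementary material and are not
redistributed with this package.
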