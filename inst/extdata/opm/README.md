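Place OPM-oriented PDB files here to enable the structural-radius
acceptance checks:

  6kr8.pdb   beta2-adrenergic receptor monomer (NMR)
  2rh1.pdb   beta2-adrenergic receptor, cholesterol-bridged crystal dimer
  4hkr.pdb   Drosophila Orai hexamer

Download from the Orientations of Proteins in Membranes (OPM) database,
which provides coordinates positioned with the membrane normal along z and
the bilayer midplane at z = 0 (DUM atoms mark the membrane surfaces). No
structure files are redistributed with this package.
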