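Synthetic 3D conformers of seven phenolic drug compounds, generated
from SMILES with Open Babel (--gen3d, MMFF94 refinement); they are NOT
the PubChem deposited conformers, so charges computed on them can
differ slightly from values computed on database geometries.
phenols.csv maps each file to the compound and its experimental
aqueous pKa.  The phenolic hydrogen is the H bonded to the hydroxyl
oxygen.
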