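# Revised JNLPBA categorical relaxation:
# DNA, RNA and protein merge into Macromolecule; cell line and cell type into Cell.
DNA	Macromolecule
RNA	Macromolecule
protein	Macromolecule
cell_line	Cell
cell_type	Cell
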