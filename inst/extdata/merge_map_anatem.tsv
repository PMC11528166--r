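# AnatEM categorical relaxation: 12 entity types down to 4 broad categories.
Organism_subdivision	Anatomical_structure
Anatomical_system	Anatomical_structure
Organ	Anatomical_structure
Multi-tissue_structure	Anatomical_structure
Tissue	Anatomical_structure
Cell	Anatomical_structure
Developing_anatomical_structure	Anatomical_structure
Cellular_component	Anatomical_structure
Organism_substance	Organism_substance
Immaterial_anatomical_entity	Immaterial_anatomical_entity
Pathological_formation	Pathological_formation
Cancer	Pathological_formation
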