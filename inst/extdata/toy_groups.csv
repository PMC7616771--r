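cell_id,group,compartment
cell1,Control,stromal
cell2,MPL,stromal
cell3,Control,stromal
cell4,MPL,stromal
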