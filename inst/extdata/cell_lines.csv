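line,dish_her2,dish_cep17,dish_n_cells,target_positive,reference_positive,total_chambers
LCL,40,40,20,383,398,770
H522,85,41,20,513,310,770
SK-BR-3,381,83,20,639,206,770
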