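(((giant_armadillo:45,(nine_banded_armadillo:25,southern_three_banded_armadillo:25):20):23,(giant_anteater:58,(two_toed_sloth:30,three_toed_sloth:30):28):10):22,(((african_elephant:8,asian_elephant:8):57,rock_hyrax:65,west_indian_manatee:65):15,(aardvark:75,((rufous_sengi:30,round_eared_sengi:30):40,(cape_golden_mole:65,((common_tenrec:20,lesser_hedgehog_tenrec:20):25,talazacs_shrew_tenrec:45):20):5):5):5):10);
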