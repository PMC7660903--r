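id	representative
Majorcapsid_f01_m01	Majorcapsid_f01_m08
Majorcapsid_f01_m02	Majorcapsid_f01_m08
Majorcapsid_f01_m03	Majorcapsid_f01_m08
Majorcapsid_f01_m04	Majorcapsid_f01_m08
Majorcapsid_f01_m05	Majorcapsid_f01_m08
Majorcapsid_f01_m06	Majorcapsid_f01_m08
Majorcapsid_f01_m07	Majorcapsid_f01_m08
Majorcapsid_f01_m08	Majorcapsid_f01_m08
Majorcapsid_f02_m01	Majorcapsid_f02_m02
Majorcapsid_f02_m02	Majorcapsid_f02_m02
Majorcapsid_f02_m03	Majorcapsid_f02_m02
Majorcapsid_f02_m04	Majorcapsid_f02_m02
Majorcapsid_f02_m05	Majorcapsid_f02_m02
Majorcapsid_f02_m06	Majorcapsid_f02_m02
Majorcapsid_f02_m07	Majorcapsid_f02_m02
Majorcapsid_f02_m08	Majorcapsid_f02_m02
Portal_f01_m01	Portal_f01_m04
Portal_f01_m02	Portal_f01_m04
Portal_f01_m03	Portal_f01_m04
Portal_f01_m04	Portal_f01_m04
Portal_f01_m05	Portal_f01_m04
Portal_f01_m06	Portal_f01_m04
Portal_f01_m07	Portal_f01_m04
Portal_f01_m08	Portal_f01_m04
Portal_f02_m01	Portal_f02_m07
Portal_f02_m02	Portal_f02_m07
Portal_f02_m03	Portal_f02_m07
Portal_f02_m04	Portal_f02_m07
Portal_f02_m05	Portal_f02_m07
Portal_f02_m06	Portal_f02_m07
Portal_f02_m07	Portal_f02_m07
Portal_f02_m08	Portal_f02_m07
others_f01_m01	others_f01_m02
others_f01_m02	others_f01_m02
others_f01_m03	others_f01_m02
others_f01_m04	others_f01_m02
others_f01_m05	others_f01_m02
others_f01_m06	others_f01_m02
others_f01_m07	others_f01_m02
others_f01_m08	others_f01_m02
others_f02_m01	others_f02_m01
others_f02_m02	others_f02_m01
others_f02_m03	others_f02_m01
others_f02_m04	others_f02_m01
others_f02_m05	others_f02_m01
others_f02_m06	others_f02_m01
others_f02_m07	others_f02_m01
others_f02_m08	others_f02_m01
Majorcapsid_f01_m01_dup	Majorcapsid_f01_m08
Majorcapsid_f02_m01_dup	Majorcapsid_f02_m02
Portal_f01_m01_dup	Portal_f01_m04
Portal_f02_m01_dup	Portal_f02_m07
others_f01_m01_dup	others_f01_m02
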