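analyte_id,site_id,pKa,site_class
DA,NH3,9.31,base
F,NH3,4.96,base
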