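drug_name,category_code,category_label
drugx,119,Other agents affecting central nervous system
drugy,421,Antineoplastics-alkylating agents
drugz,235,Purgatives and clysters
drugq,625,Anti-virus agents
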