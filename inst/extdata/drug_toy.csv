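case_id,version,drug_seq,role,drug_name
C01,1,1,suspected,drugx
C02,1,1,suspected,drugx
C03,1,1,suspected,drugx
C04,1,1,suspected,drugx
C05,1,1,suspected,drugy
C06,1,1,suspected,drugy
C07,1,1,suspected,drugy
C08,1,1,suspected,drugz
C09,1,1,suspected,drugz
C10,1,1,concomitant,drugx
C11,1,1,concomitant,drugy
C12,1,1,interacting,drugz
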