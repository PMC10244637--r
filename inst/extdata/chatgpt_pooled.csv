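item_id,set_label,solution_rate,answer
practice_01,practice,0.5,0
practice_02,practice,0.211,0
practice_03,practice,0.75,1
practice_04,practice,0.2,0
practice_05,practice,0.65,0
practice_06,practice,0.65,1
practice_07,practice,0.19,0
practice_08,practice,0.55,1
practice_09,practice,0.65,0
practice_10,practice,0.1,0
practice_11,practice,0.556,1
practice_12,practice,0.579,0
practice_13,practice,0.286,1
practice_14,practice,0.5,1
practice_15,practice,0.6,1
transfer_01,transfer,0.4,1
transfer_02,transfer,0.45,0
transfer_03,transfer,0.364,0
transfer_04,transfer,0.4,0
transfer_05,transfer,0.3,0
transfer_06,transfer,0.3,1
transfer_07,transfer,0.421,0
transfer_08,transfer,0.35,1
transfer_09,transfer,0.3,0
transfer_10,transfer,0.318,0
transfer_11,transfer,0.35,0
transfer_12,transfer,0.368,1
transfer_13,transfer,0.3,1
transfer_14,transfer,0.4,0
transfer_15,transfer,0.318,0
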