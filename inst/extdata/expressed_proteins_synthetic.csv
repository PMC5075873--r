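reaction_id,expressed
R1,1
R2,0
R3,1
R4,0
R5,0
R6,1
R7,0
R8,1
R9,0
R10,0
R11,0
R12,0
R13,0
R14,1
R15,0
R16,1
R17,0
R18,0
R19,1
R20,0
R21,0
R22,1
R23,0
R24,0
R25,0
R26,0
R27,1
R28,0
R29,0
R30,0
R31,0
R32,0
R33,0
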