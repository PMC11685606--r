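STRESS01
STRESS02
STRESS03
STRESS04
STRESS05
STRESS06
STRESS07
STRESS08
STRESS09
STRESS10
STRESS11
STRESS12
STRESS13
STRESS14
STRESS15
STRESS16
STRESS17
STRESS18
STRESS19
STRESS20
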