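[PAD]
[UNK]
[CLS]
[SEP]
[MASK]
su
##xa
##met
##hon
##ium
masseter
spasm
a
dose
response
study
-
.
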