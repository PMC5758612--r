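participant,group,trained
AMD1,MD,TRUE
AMD2,MD,TRUE
AMD3,MD,TRUE
AMD4,MD,TRUE
AMD5,MD,FALSE
C1,control,TRUE
C2,control,TRUE
C3,control,FALSE
C4,control,TRUE
C5,control,FALSE
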