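>species01
LKSILLPFRMPASRAMESSPWYARTMTLSNLEVRDEPFAFSRAESRFYSYAKWCDRASALSPGRVRGILGCHIPFQNLTS
CGRKLSNPH
>species02
TKSILLPFREDASRAKESSPWYARTRTVSNLESRDEPFAFSAAESRTYSYAKWCDRAQAERPGTVRGILGCHIPGQNLTS
CGRKLSNPH
>species03
TKSILLPFREPASRADESSPWYAYTRFLSNLESRDNPFAFSRAESRTYSYAGWCDFACAESPGRVRGILGCHIPGQNLTS
CGRKLNNPA
>species04
TKYILLPFREPASRAMESSRWYARTRTLSNLESRDEPFAFSRAEKRTYSYAKWCDRASDESPWRVRGILGCHIPGQNLTS
CGRKLSAPC
>species05
HKSILLPFTEPASRAMESSPWYARCRTLSNLESRDEPFAFSRAESRTYSYAKWCDRASAEDPSRVRGILGCHIPGQNWTS
CGRQLSNPH
>species06
IKSILLAFREPASRAMETSSWYARTRTLSNLESRDEPFAFYRAESRTYRYAKWCDRASAESPGRVRGIWGCHIPGCNLTS
CGTKLSNPH
>species07
TKNILLEFREPASRAMESSPWYARTRTLSNSESRDEGFAFSRAESRTYSYAKCNDRASATSPGRVRGILGCHIPGQNLTS
CGRKLSAPH
>species08
TKSILLPFREPASRAMESSCWYARTRTLSNLHSRDEPFAFSRAESRTYSYAKWCDRASAQSPGEVRGILGCHIHGQNLTS
LGRKLSNWH
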