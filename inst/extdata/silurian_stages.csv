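# Silurian stage boundaries (Ma, rounded); intervals are half-open
# [start_ma, end_ma).  User-editable: no timescale is baked into the code.
name,start_ma,end_ma
Rhuddanian,443.8,440.8
Aeronian,440.8,438.5
Telychian,438.5,433.4
Sheinwoodian,433.4,430.5
Homerian,430.5,427.4
Gorstian,427.4,425.6
Ludfordian,425.6,423.0
Pridoli,423.0,419.2
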