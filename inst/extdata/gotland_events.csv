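# Event windows: the oldest and youngest assemblages bracketing each of
# the three Silurian crisis events, made explicit as user input.
name,oldest,youngest
Ireviken,Ireviken,Lickershamn
Mulde,Svarvare,Mulde Tegelbruk
Lau,Gannor,Lau backar
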