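class	keyword
PLASMA_MEMBRANE	cell membrane
PLASMA_MEMBRANE	plasma membrane
PLASMA_MEMBRANE	cell surface
SECRETED	secreted
SECRETED	extracellular space
ER	endoplasmic reticulum
GOLGI	golgi
LYSOSOME	lysosome
LYSOSOME	lysosomal
NUCLEAR_MEMBRANE	nucleus membrane
NUCLEAR_MEMBRANE	nuclear membrane
NUCLEAR_MEMBRANE	nuclear envelope
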