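# Gazetteer exclusion terms: surface forms that contain or resemble
# outcome aliases but denote a different quantity (aortic valve area,
# indexed area, prosthesis identifiers). A match consumes the tokens so
# that no outcome lookup can fire inside them. One surface per line.
AVA (VTI)
AVA VTI
AVAi (VTI)
AVAi VTI
AVA
AVAi
AVR
MVR
TAVI
TAVR
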