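"id","class"
"bcell01","bcell_like"
"bcell02","bcell_like"
"bcell03","bcell_like"
"bcell04","bcell_like"
"neutrophil01","neutrophil_like"
"neutrophil02","neutrophil_like"
"neutrophil03","neutrophil_like"
"neutrophil04","neutrophil_like"
"tcell01","tcell_like"
"tcell02","tcell_like"
"tcell03","tcell_like"
"tcell04","tcell_like"
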