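# Preferred terms listed on the irinotecan label (expectedness reference).
diarrhoea
neutropenia
thrombocytopenia
stomatitis
enteritis
nausea
vomiting
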