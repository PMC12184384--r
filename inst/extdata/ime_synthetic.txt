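# Synthetic stand-in for the EMA Important Medical Events list
# (illustrative subset only; the licensed list is a user-supplied input).
febrile neutropenia
sepsis
septic shock
interstitial lung disease
hyperammonaemia
dehydration
pt_001
pt_004
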