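# Synthetic stand-in for the EMA Designated Medical Events list
# (illustrative subset only).
hepatic failure
agranulocytosis
toxic epidermal necrolysis
second primary malignancy
pt_002
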