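# Drug-name search lexicon for the irinotecan extraction (FAERS dialect).
# Matching is exact after trim / whitespace-collapse / case-fold.
IRINOTECAN
IRINOTECAN HCL
IRINOTECAN HYDROCHLORIDE
CPT 11 IRINOTECAN
CPT 11
CAMPTOSAR
CAMPTO
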