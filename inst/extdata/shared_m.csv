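# Shared m-values from the global two-state fits.
# urea: kcal mol^-1 M^-1 (NCBD variants); tfe: per % (CID variants).
mode,m_shared,se
urea,0.61,0.05
tfe,0.17,0.01
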