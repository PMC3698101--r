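# Section-code registry: maps section codes found in SPL-dialect XML to
# the three sections claims are routed to. Codes are deployment-specific;
# these synthetic defaults match the fixture generator's output.
clinical_studies: SEC-CS
drug_interactions: SEC-DI
clinical_pharmacology: SEC-CP
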