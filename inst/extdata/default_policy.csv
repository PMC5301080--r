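atc_prefix,allowed_categories,note
N05A,schizophrenia_psychosis,psychotic-spectrum diagnoses license every antipsychotic
N05AH04,schizophrenia_psychosis;mood,quetiapine additionally licensed in mood disorders
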