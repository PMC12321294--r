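# Default flattening map for Beacon v2 genomic-variant documents
# (copy-number calls: interbase coordinates, EFO variant states).
entity: g_variants
columns:
  - name: variant_id
    path: variantInternalId
  - name: analysis_id
    path: analysisId
  - name: biosample_id
    path: biosampleId
  - name: chromosome
    path: location.referenceName
  - name: start
    path: location.start
  - name: end
    path: location.end
  - name: variant_state_id
    path: variantState.id
  - name: variant_state
    path: variantState.label
  - name: log2
    path: info.log2
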