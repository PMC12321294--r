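# Default flattening map for Beacon v2 individual documents.
# Column inventory follows the Progenetix-style default data model; beacons
# with different layouts can supply their own config (see ?load_mapping).
entity: individuals
columns:
  - name: individual_id
    path: id
  - name: sex
    path: sex.label
  - name: sex_id
    path: sex.id
  - name: vital_status
    path: vitalStatus.label
  - name: followup_time
    path: followupTime
  - name: diseases
    path: diseases[].diseaseCode.id
    cardinality: join
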