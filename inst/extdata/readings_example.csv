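subject_id,timestamp,sbp,dbp,pulse,context
W001,2017-03-01T09:15:00,118,75,72,antenatal
W002,2017-03-01T09:40:00,162,95,70,antenatal
W003,2017-03-01T10:05:00,100,60,95,postnatal
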