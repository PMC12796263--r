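# Example pipeline configuration. Omitted keys keep the package defaults
# (see ?pipeline_config); unknown keys are rejected.
delta_diff_min: 0.05      # criterion 1: |treated - untreated| PRAISE(+) rate
praise_minus_max: 0.05    # criterion 2: ceiling on PRAISE(-) rates
p_max: 0.005              # criterion 3: Fisher exact p cutoff
delta_increase_min: 0.10  # criterion 4: signed treated-over-untreated increase
max_mismatches: 3
min_umi_family: 3
max_read_mismatches: 2
te_min_rna_cpm: 1
te_min_ribo_count: 20
rep_filter_log2: 1.0
min_depth: 20
p_site_offset: 12
rrts_event_threshold: 0.01
top_k: 50
seed: 1
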