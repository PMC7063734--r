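# Template configuration for the nine major CLL stereotyped subsets that
# use IGHV1-family genes. The consensus VH CDR3 patterns and offsets are
# NOT distributed with this package: they must be completed from the
# published subset definitions in the immunogenetics literature
# (pattern: null entries below make read_subset_definitions() fail with a
# pointer to this file). cdr3_length_aa values and typical gene usage
# reflect the commonly reported subset features; verify against the
# definitions you fill in. Tests and examples use synthetic definitions
# instead of this template.
subsets:
  - subset_id: "#1"
    cdr3_length_aa: 13
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-2", "IGHV1-3", "IGHV1-18", "IGHV1-8"]
  - subset_id: "#1-99"
    cdr3_length_aa: 13
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-2"]
  - subset_id: "#3"
    cdr3_length_aa: 22
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-69"]
  - subset_id: "#5"
    cdr3_length_aa: 20
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-69"]
  - subset_id: "#6"
    cdr3_length_aa: 21
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-69"]
  - subset_id: "#7H"
    cdr3_length_aa: 13
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-69"]
  - subset_id: "#12"
    cdr3_length_aa: 19
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-69"]
  - subset_id: "#28A"
    cdr3_length_aa: 15
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-69"]
  - subset_id: "#59"
    cdr3_length_aa: 14
    pattern: null
    pattern_offset: 0
    clan: I
    typical_v_genes: ["IGHV1-58"]
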