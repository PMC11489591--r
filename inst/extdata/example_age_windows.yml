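# Example age-window definitions (ka) for interval_stats(), following the
# conventional marine isotope stage (MIS) chronology. Window boundaries are
# user configuration, not package constants - adjust to the record's age
# model before use.
holocene: [0, 11.7]
lgm: [19, 26.5]
mis5e: [116, 129]
mis9: [300, 337]
mis11: [374, 424]
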