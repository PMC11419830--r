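# Scan settings and locus definitions for the CTG18.1 repeat (hg38).
motif: CTTAAG
resolution_limit: 1000
loci:
  CTG18.1:
    contig: chr18
    upstream_id: 10414
    downstream_id: 10415
    ref_repeats: 24
    unit: 3
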