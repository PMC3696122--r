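- name: TaqIA
  gene: ANKK1
  kind: SNP
  alleles:
  - C
  - T
  grouping_allele: T
- name: TaqIB
  gene: DRD2
  kind: SNP
  alleles:
  - A
  - G
  grouping_allele: A
- name: DRD4_521
  gene: DRD4
  kind: SNP
  alleles:
  - C
  - T
  grouping_allele: C
- name: DRD4_615
  gene: DRD4
  kind: SNP
  alleles:
  - A
  - G
  grouping_allele: G
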