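# Default 37-locus Y-STR panel: union of the Yfiler Plus and PowerPlex Y23
# marker sets plus eight additional single markers. DYS385 and DYF387S1 are
# duplicated (multi-copy) markers; each copy counts as one locus, giving
# 33 + 2x2 = 37 loci. The uniform rate below is the assumed average
# mutation rate per locus per generation.
mu: 0.0039
loci:
  - {name: DYS19}
  - {name: DYS385, multicopy: true}
  - {name: DYS389I}
  - {name: DYS389II}
  - {name: DYS390}
  - {name: DYS391}
  - {name: DYS392}
  - {name: DYS393}
  - {name: DYS437}
  - {name: DYS438}
  - {name: DYS439}
  - {name: DYS448}
  - {name: DYS449}
  - {name: DYS456}
  - {name: DYS458}
  - {name: DYS460}
  - {name: DYS481}
  - {name: DYS518}
  - {name: DYS533}
  - {name: DYS549}
  - {name: DYS570}
  - {name: DYS576}
  - {name: DYS627}
  - {name: DYS635}
  - {name: DYS643}
  - {name: DYF387S1, multicopy: true}
  - {name: YGATAH4}
  - {name: DYS504}
  - {name: DYS525}
  - {name: DYS552}
  - {name: DYS505}
  - {name: DYS537}
  - {name: DYS445}
  - {name: Y-GATA-A10}
  - {name: GGAAT1B07}
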