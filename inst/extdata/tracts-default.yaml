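# Default white-matter tract map over the six core regions.
# A convenience fixture encoding canonical curving/projection fiber
# connections (thalamocortical and cortico-basal loops), NOT tractography
# ground truth; supply your own map for real analyses.
tracts:
  - [Tha, BG]
  - [Tha, Cere]
  - [Tha, PFC]
  - [Tha, VC]
  - [BG, SMA]
  - [PFC, SMA]
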