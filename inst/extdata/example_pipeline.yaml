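# Example pipeline configuration for a real-data screen.
#
# The bootscan parental sets below follow the usual design for this kind of
# screen: the query is one modern haplogroup representative (or the rCRS) and
# the candidate parentals mix Neanderthal and archaic-AMH genomes, e.g.
#   query rCRS      : parentals Mezmaiskaya 1, Altai, Fumane 2, Ust-Ishim
#   query L0d1a/L3d3b: parentals Feldhofer 1, Mezmaiskaya 1, Vindija 33.16,
#                      Kostenki 14, Fumane 2, Dolni Vestonice 14, Tianyuan
# Sample ids must match the FASTA/metadata ids.

input:
  fasta: alignment.fasta          # rCRS-anchored multi-FASTA
  metadata: metadata.tsv          # sample_id  clade  subclade_label
  reference_id: rCRS
  include_reference: true

stages:
  variants: true
  annotation: true
  patterns: true
  clock: true
  pca: true
  bootscan: true

clock:
  subs_per_10ky: 4.14             # ancient-DNA calibrated whole-genome rate
  changes_per_10ky: 1             # populational calibration

pca:
  k: 2
  regions:
    - [128, 315]
    - [6950, 7660]

bootscan:
  query: rCRS
  parentals: [Mezmaiskaya1, Altai, Fumane2, UstIshim]
  window_size: 200
  step_size: 20
  replicates: 1000
  cutoff_percent: 70
  distance_model: K80

output_dir: mitosig_out
seed: 1
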