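Curated reference tables from a published screen of 339 candidate skeletal
muscle cis-regulatory modules assayed by dual-luciferase reporter transfection
in C2C12 cells.

validated_regions.tsv
  The 19 insert sequences validated as driving myotube-selective expression.
  Coordinates are 1-based inclusive (hg18) as conventionally printed; convert
  with table_to_bed() before interval arithmetic. positive_wells gives
  "positive clones / available clones" for the consensus rule; the last three
  columns flag which prediction program(s) covered the region.

motif_overrepresentation_counts.tsv
  Region-level TFBS hit/non-hit counts for the three over-representation
  comparisons of validated versus non-responding regions, with the published
  Z and Fisher columns retained for reference. The Fisher column is the
  one-sided (enrichment) hypergeometric tail of the printed counts.

myod_overlap_counts.tsv
  Counts of regions (lifted to mm9) overlapping MyoD ChIP-seq peaks in C2C12
  myoblasts and myotubes, for responding and non-responding region sets.
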