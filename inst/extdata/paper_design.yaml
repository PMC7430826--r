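# Spike-in mixture design: three plant backgrounds at 30% each, three
# bacterial "contaminant" backgrounds at 3.3% each (proportions are
# renormalized to fill whatever the spike leaves), a 9-point spike series,
# and a desk-scale mixture depth of 220,000 reads. Paths are resolved
# relative to this file; replace them with your own read pools.
total_reads: 220000
fractions: [5, 2.5, 1.25, 0.6, 0.3, 0.15, 0.07, 0.03, 0.01]
components:
  - {label: plant_bg1, path: plant_bg1.fastq.gz, proportion: 30}
  - {label: plant_bg2, path: plant_bg2.fastq.gz, proportion: 30}
  - {label: plant_bg3, path: plant_bg3.fastq.gz, proportion: 30}
  - {label: bact_bg1, path: bact_bg1.fastq.gz, proportion: 3.3}
  - {label: bact_bg2, path: bact_bg2.fastq.gz, proportion: 3.3}
  - {label: bact_bg3, path: bact_bg3.fastq.gz, proportion: 3.3}
spike:
  label: target_sp
  path: target_reads.fastq.gz
  fraction: 5
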