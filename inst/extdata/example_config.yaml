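# Example run configuration: desk-scale CcPub.1 pgSIT releases at ratio 1,
# batched every 2 weeks. Omitted sim fields take the published defaults.
sim:
  scale_factor: 0.1
  burn_in_weeks: 50
  horizon_weeks: 100
profile:
  name: CcPub1_pgSIT
schedule:
  release_ratio: 1
  interval_weeks: 2
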