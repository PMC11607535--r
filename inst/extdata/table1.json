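{
  "labels": ["ADAS-cog", "HippoV", "CSFtau", "AV45"],
  "A": [
    [0, -0.23286, 0.04579, 0.11301],
    [0, 0, 0, -0.06553],
    [0, 0, 0, 0.01371],
    [0, 0, 0, 0]
  ],
  "c": [-0.08587, -0.42319, 0.10595, 0.19057]
}
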