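grid_size: 100
mask:
  cells: []
assignments: []
default_input: 0.0
duration: 500
snapshots:
- 0
- 100
- 300
- 500
fixed_dt: 0.1
name: case01_baseline
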