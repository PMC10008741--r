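# Small demonstration scene for `ulm3d run --config demo.yaml`:
# a 1-generation vessel tree on a reduced grid, processed end-to-end
# (simulate -> svdfilter -> localize -> track) in well under a minute.
seed: 1
stages: [simulate, svdfilter, localize, track]
scene:
  grid:
    origin: [0.3, -1.4, -1.4]
    dim: [20, 28, 28]
  tree:
    nGenerations: 1
    rootRadius: 0.06
    rootPeakSpeed: 25
    branchAngle: 30
    rootStart: [0.8, -1.0, -0.4]
    rootDirection: [0.3, 1.0, 0.2]
    lengthFactor: 16
  bubbles:
    duration: 0.4
    meanBubblesInView: 6
  noise:
    clutterChunkFrames: 100
    clutterTemporalModes: 14
svd:
  blockSize: 100
track:
  minTrackLength: 5
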