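Golden regression fixtures (synthetic; base64-encoded BBI bytes).
Each file regenerates deterministically from the package's seeded
generators; the committed bytes pin the on-disk format.

golden-track.bw.b64      writeBigWig of genSignalTrack(trackSpec(seed=42,
                         chromSizes=c(ctg1=4000, ctg2=2500), n=120,
                         lengthRange=c(5,50), valueRange=c(0,10),
                         gapProb=0.2)), default bbiWriteOptions()
golden-track-be.bw.b64   same track, bbiWriteOptions(endian="big",
                         compress=FALSE)
golden-features.bb.b64   writeBigBed of genFeatures(featureSpec(seed=42,
                         same chromSizes, n=80, layout="bed6")) with the
                         stock bed6 autoSql schema embedded
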