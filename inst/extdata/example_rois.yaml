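# ROI layout matching the default synthetic scene at 96 x 128 px
# (0-based, half-open rectangles). For clinical 640 x 512 recordings
# the mouth ROI is conventionally 250 x 200 px in front of the mouth.
chest_roi: {x: 6, y: 47, width: 64, height: 44}
mouth_roi: {x: 79, y: 14, width: 38, height: 29}
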