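# Retained landmark features after Monte-Carlo RFECV stability selection
# (published result of the pilot study; '~' denotes an inclusive range,
# x = horizontal coordinate, y = vertical coordinate).
contour: x1 ~ x17, y1 ~ y17
eyebrow: x18, x19, x20, x23 ~ x27, y18 ~ y27
nose: x31, x32, y30, y31, y34
eye: x37, y37, y38, y39, y48, y44, y45, y46
mouth: x49, x57 ~ x61, y49, y50, y52 ~ y59, y61, y63
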