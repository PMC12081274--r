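>SYNTH_CTCF synthetic CTCF-like motif (constructed for this package)
A  [ 202 171 720 68 32 970 22 900 68 180 45 22 14 32 54 840 126 171 202 ]
C  [ 550 620 126 50 930 14 16 45 50 132 33 950 10 930 40 72 92 125 148 ]
G  [ 148 125 92 850 23 10 950 33 850 600 900 16 970 23 26 53 720 84 550 ]
T  [ 100 84 62 32 15 6 12 22 32 88 22 12 6 15 880 35 62 620 100 ]
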