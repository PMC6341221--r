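# synthetic example of a SOAX-style network result (pixel coordinates)
# three snakes crossing near (100, 100) and (160, 120)
s p x y z intensity
1 1 40 100 0 612
1 2 70 100 0 598
1 3 100 100 0 1140
1 4 130 100 0 605
1 5 160 100 0 590
2 1 100 40 0 571
2 2 100 70 0 588
2 3 100 100 0 1152
2 4 100 130 0 602
2 5 100 160 0 615
3 1 120 60 0 433
3 2 140 90 0 428
3 3 160 120 0 856
3 4 180 150 0 440
#junctions
100 100 0
101 101 0
160 120 0
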