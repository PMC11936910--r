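dose,crcl,plt,p_below,p_window,p_above
50,30,85,35.2,58,6.8
50,60,85,51.8,45,3.2
50,90,85,64.4,33.8,1.8
50,120,85,69.9,29,1.1
50,150,85,76.4,22.7,0.9
50,30,266,24.3,59.4,16.3
50,60,266,37.2,55.8,7
50,90,266,50.2,45.2,4.6
50,120,266,55.5,41.2,3.3
50,150,266,63.8,34,2.2
75,30,85,8.3,58.9,32.8
75,60,85,17.4,61.4,21.2
75,90,85,25.8,60,14.2
75,120,85,30.6,59.9,9.5
75,150,85,37.3,55.3,7.4
75,30,266,3.7,46.2,50.1
75,60,266,10.5,57,32.5
75,90,266,16.8,60.7,22.5
75,120,266,20.5,61.1,18.4
75,150,266,25.6,60.8,13.6
100,30,85,2.2,33.8,64
100,60,85,4.4,48,47.6
100,90,85,8.4,56.7,34.9
100,120,85,13.4,56.7,29.9
100,150,85,15.6,61,23.4
100,30,266,0.6,24.2,75.2
100,60,266,2.3,35.5,62.2
100,90,266,4.7,46,49.3
100,120,266,6.2,50,43.8
100,150,266,8.4,55.9,35.7
125,30,85,0.5,17,82.5
125,60,85,1.4,29.2,69.4
125,90,85,3.2,38.2,58.6
125,120,85,4.8,42,53.2
125,150,85,4.9,50.6,44.5
125,30,266,0.1,10.4,89.5
125,60,266,0.4,20.6,79
125,90,266,1.4,28.8,69.8
125,120,266,2,32.8,65.2
125,150,266,2.6,39.2,58.2
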