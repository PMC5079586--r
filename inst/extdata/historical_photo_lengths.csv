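photo,source,year,fish,tl_cm
1,Stein Hoff,1925,1,65.3
1,Stein Hoff,1925,2,76.0
1,Stein Hoff,1925,3,76.3
2,R. Blomberg,1934,4,60.3
2,R. Blomberg,1934,5,112.6
2,R. Blomberg,1934,6,82.7
3,R. Blomberg,1934,7,61.4
4,R. Blomberg,1934,8,62.8
4,R. Blomberg,1934,9,43.5
5,R. Blomberg,1934,10,74.2
5,R. Blomberg,1934,11,115.0
5,R. Blomberg,1934,12,83.2
6,R. Blomberg,1934,13,70.1
7,R. Blomberg,1934,14,70.4
7,R. Blomberg,1934,15,69.2
7,R. Blomberg,1934,16,78.6
7,R. Blomberg,1934,17,86.3
7,R. Blomberg,1934,18,77.0
7,R. Blomberg,1934,19,61.1
7,R. Blomberg,1934,20,74.4
8,A. Hancock,1938,21,87.8
8,A. Hancock,1938,22,91.7
8,A. Hancock,1938,23,76.7
8,A. Hancock,1938,24,71.0
8,A. Hancock,1938,25,87.1
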