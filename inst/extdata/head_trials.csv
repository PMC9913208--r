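horse,N,dV,dP,Vsc,Vmc,Psc,Pmc,sVsc,sVmc,sPsc,sPmc,Rmc
1,16,-0.4,-4.8,-1.5,-1.1,13.1,17.9,15.2,15.4,18.1,16.5,66.6
2,23,-2.1,8.7,-9.4,-7.3,43.0,34.3,12.3,10.4,19.7,20.8,82.2
3,29,2.3,-1.9,-1.6,-3.9,9.5,11.4,17.7,15.0,13.6,14.1,70.4
4,38,4.1,3.4,-39.8,-44.0,-0.8,-4.2,14.3,15.7,14.8,16.8,71.2
5,28,-0.3,2.2,70.0,70.3,-17.5,-19.8,17.4,15.2,17.2,14.5,109.6
6,26,4.4,5.7,-39.2,-43.6,-3.9,-9.6,16.8,19.1,15.8,15.8,68.5
7,19,3.3,-3.1,5.4,2.1,3.3,6.3,13.5,14.2,19.9,21.1,77.5
8,22,-0.6,-3.7,7.1,7.7,8.8,12.5,15.7,11.9,11.0,10.4,73.6
9,29,1.0,-5.0,-39.7,-40.7,15.7,20.6,9.1,10.6,9.5,10.0,70.8
10,36,-0.6,0.6,1.8,2.4,-19.1,-19.8,22.3,22.0,20.7,21.4,95.2
11,27,0.0,0.4,-57.8,-57.9,13.0,12.5,11.5,13.1,16.4,15.2,90.1
12,28,-2.5,1.9,-11.7,-9.2,-18.5,-20.4,14.3,13.5,17.5,14.9,71.0
13,22,-0.0,1.6,62.8,62.8,-3.7,-5.3,8.9,8.2,10.8,10.3,79.8
14,22,0.3,-0.9,-1.6,-1.9,8.7,9.6,9.7,13.8,6.1,10.6,39.0
15,29,1.5,-1.8,27.0,25.5,-14.1,-12.4,13.8,13.1,11.2,11.6,75.2
16,19,-6.8,0.2,22.8,29.6,10.9,10.7,19.1,26.2,18.6,28.1,75.5
17,34,-0.2,-3.7,3.7,3.9,-4.2,-0.5,18.9,17.5,19.6,18.7,95.0
18,24,1.8,-3.1,14.9,13.1,-13.1,-10.1,8.3,7.9,13.6,11.4,57.9
19,35,-0.4,-2.1,0.2,0.6,24.2,26.3,6.9,6.4,8.6,6.0,51.0
20,41,-0.5,1.7,-21.6,-21.0,7.0,5.3,11.9,12.6,9.1,8.5,71.4
21,16,-0.4,1.2,-23.5,-23.0,5.8,4.6,8.4,7.7,6.7,7.4,43.0
22,36,2.2,-1.8,-13.0,-15.2,-1.5,0.3,8.5,8.2,12.3,10.5,50.9
23,56,-4.2,-0.1,-18.2,-14.0,-16.3,-16.2,18.7,17.6,18.8,18.9,74.7
mean,28.5,1.7,2.6,21.5,21.8,12.0,12.6,13.6,13.7,14.3,14.5,72.2
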