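horse,N,dV,dP,Vsc,Vmc,Psc,Pmc,sVsc,sVmc,sPsc,sPmc,Rmc
1,13,1.0,-0.1,-0.1,-1.1,6.6,6.6,8.4,6.1,8.2,8.3,83.4
2,15,1.7,4.3,-0.4,-2.1,0.6,-3.8,11.0,8.6,10.0,8.6,82.3
3,16,-1.8,2.1,-0.6,1.2,-2.7,-4.8,6.5,4.0,8.9,5.6,82.6
4,24,4.3,6.5,-15.8,-20.1,21.0,14.5,9.3,7.9,9.6,8.1,92.5
5,17,5.5,-0.5,5.7,0.2,4.3,4.8,5.1,4.3,10.3,11.3,79.3
6,15,4.8,5.9,-12.8,-17.6,27.2,21.3,11.0,7.5,8.9,6.3,92.8
7,17,1.5,0.0,-0.1,-1.5,-5.2,-5.2,6.8,6.9,10.5,8.5,74.8
8,13,1.1,3.1,2.1,1.0,-8.6,-11.6,8.0,8.1,9.2,4.7,76.7
9,15,-0.8,2.2,-13.0,-12.2,-4.3,-6.5,7.1,4.6,6.0,6.0,67.5
10,22,4.6,2.1,9.0,4.4,2.2,0.1,6.5,7.7,15.8,16.0,77.7
11,15,-1.7,0.7,-7.0,-5.3,-11.9,-12.6,6.4,8.3,10.2,9.6,88.0
12,14,-0.9,1.1,-4.5,-3.6,2.6,1.5,6.4,4.8,7.3,7.9,64.7
13,11,3.9,2.4,-12.6,-16.5,9.0,6.6,9.7,6.9,8.1,8.5,70.8
14,14,1.3,0.9,-5.1,-6.4,13.0,12.0,5.8,6.7,9.0,8.6,74.8
15,14,-2.3,-3.0,5.8,8.1,-16.9,-13.9,5.7,3.1,6.0,3.3,75.3
16,13,4.2,-1.1,11.8,7.7,-25.8,-24.7,10.5,13.0,13.8,8.7,75.7
17,18,-1.4,-0.8,-10.6,-9.3,-1.4,-0.6,12.2,11.2,11.4,11.5,103.7
18,15,-3.2,-0.3,-2.8,0.4,-13.1,-12.8,5.6,4.6,7.1,3.3,85.5
19,26,1.2,-1.2,-9.6,-10.8,4.4,5.6,3.6,3.4,4.3,4.6,39.6
20,21,-4.9,1.3,-7.2,-2.3,0.1,-1.2,6.5,6.6,11.6,9.0,87.8
21,21,0.8,2.6,-38.0,-38.9,48.5,46.0,7.1,6.8,12.7,8.6,97.7
22,25,-1.5,2.8,-10.2,-8.7,-1.4,-4.2,6.6,5.1,5.5,6.1,67.0
23,30,1.0,0.4,-21.5,-22.6,12.5,12.1,8.9,9.8,8.8,8.0,72.6
mean,17.6,2.4,2.0,9.0,8.8,10.6,10.1,7.6,6.8,9.3,7.9,78.8
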